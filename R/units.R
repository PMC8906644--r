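# Internal unit conventions: lengths um, time s (rates quoted per hour where
# stated), concentrations mM, pressures kPa, biomass fg.  All conversions live
# here so the rest of the package never multiplies by raw powers of ten.

# 1 um^3 * mM = 1e-15 L * 1e-3 mol/L = 1e-18 mol
.UM3MM_PER_MOL <- 1e18

# substrate is modelled as glucose: 180 g/mol = 1.8e17 fg/mol
.SUBSTRATE_FG_PER_MOL <- 1.8e17

# fg of substrate carried by one um^3*mM of solution
.SUBSTRATE_FG_PER_UM3MM <- .SUBSTRATE_FG_PER_MOL / .UM3MM_PER_MOL # 0.18

# full aerobic respiration of glucose: 6 mol O2 per mol substrate
.O2_PER_SUBSTRATE_MOL <- 6

.hours_to_seconds <- function(h) h * 3600
.seconds_to_hours <- function(s) s / 3600

# meniscus curvature radius from Young-Laplace, in um
# gamma in N/m, psi in kPa (<= 0); r_c = gamma / |psi|
.curvature_radius_um <- function(gamma, psi_kpa) {
  if (psi_kpa == 0) return(Inf)
  gamma * 1000 / abs(psi_kpa)
}
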