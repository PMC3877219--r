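# Generates the plain-text parameter files shipped under inst/extdata/.
# The functional forms follow the published additive shift model (cosine
# series in phi/psi, exponential-times-angular hydrogen-bond perturbations,
# point-dipole ring currents, exponential trans-hydrogen-bond coupling); the
# coefficient VALUES are a synthetic parameterization chosen once to give
# physically realistic magnitudes, since the original fitted coefficients are
# not published in machine-readable form. Files carry `synthetic` in their
# names for that reason. Run from the package root:
#   Rscript data-raw/make_parameter_files.R

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

hdr <- function(path, lines) {
  writeLines(c(paste0("# ", lines)), path)
}

wtable <- function(df, path, comment) {
  con <- file(path, "w")
  writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

# 1. Backbone phi/psi cosine series -----------------------------------------
# value = sum coeff * f(kphi * phi) * g(kpsi * psi), basis "cc" = cos*cos,
# "cs" = cos*sin, "sc" = sin*cos, "ss" = sin*sin.
backbone <- data.frame(
  kphi = c(0, 1, 0, 1, 0, 1, 1, 2, 0),
  kpsi = c(0, 0, 1, 0, 1, 1, 1, 0, 2),
  basis = c("cc", "cc", "cc", "sc", "cs", "cc", "ss", "cc", "cc"),
  coeff = c(4.60, 0.55, -0.45, 0.30, -0.35, 0.25, -0.40, 0.12, 0.18)
)
wtable(backbone, "inst/extdata/backbone_series_synthetic.tsv", c(
  "Backbone amide proton shift: truncated 2-D cosine series over (phi, psi).",
  "Synthetic parameterization (realistic magnitudes; original fit not published).",
  "Columns: kphi kpsi basis coeff; basis letters select cos/sin per axis."))

# 2. Ring-current intensities ------------------------------------------------
rings <- data.frame(
  kind = c("PHE6", "TYR6", "TRP5", "TRP6", "HIS5"),
  intensity = c(1.00, 0.81, 0.90, 1.04, 0.68)
)
wtable(rings, "inst/extdata/ring_intensities_synthetic.tsv", c(
  "Point-dipole ring-current intensity factors per aromatic ring type",
  "(dimensionless, benzene = 1). Synthetic defaults on the literature scale."))

# 3. Amide-amide primary hydrogen-bond closed form ---------------------------
# delta(ppm) = exp(-k * r_HO) * (a * cos^2(theta2) + b), theta2 = H...O=C.
# none_value: term for solvent-exposed protons (water/N-methylacetamide
# minimum-energy geometry).
primary <- data.frame(
  param = c("k", "a", "b", "none_value"),
  value = c(2.0, 120, 60, 2.07)
)
wtable(primary, "inst/extdata/hb_amide_primary_synthetic.tsv", c(
  "Primary hydrogen-bond shift perturbation, amide-amide closed form:",
  "delta = exp(-k*r_HO) * (a*cos^2(theta_HOC) + b)  [ppm; r in Angstrom].",
  "none_value is the fixed solvent-exposed (water-model) term in ppm.",
  "Synthetic coefficients; functional form exponential x angular."))

# 4. Lookup grids for carboxylate / alcohol acceptors -------------------------
make_grid <- function(k, a, b) {
  r <- seq(1.4, 4.0, by = 0.2)
  ang <- seq(90, 180, by = 10)
  g <- expand.grid(r = r, angle = ang)
  g$value <- exp(-k * g$r) * (a * cos(g$angle * pi / 180)^2 + b)
  g
}
wtable(make_grid(2.2, 170, 85), "inst/extdata/hb_carboxylate_grid_synthetic.tsv", c(
  "Primary-bond shift perturbation grid, carboxylate acceptors",
  "(N-methylacetamide/acetate-like scan). Columns: r (A), angle (deg, H...O=C),",
  "value (ppm). Bilinear interpolation between nodes; synthetic values."))
wtable(make_grid(2.1, 130, 55), "inst/extdata/hb_alcohol_grid_synthetic.tsv", c(
  "Primary-bond shift perturbation grid, alcohol acceptors",
  "(N-methylacetamide/methanol-like scan). Columns as carboxylate grid;",
  "synthetic values."))

# 5. Secondary hydrogen-bond closed form -------------------------------------
secondary <- data.frame(param = c("k", "a", "b"), value = c(2.2, 30, 18))
wtable(secondary, "inst/extdata/hb_secondary_synthetic.tsv", c(
  "Secondary hydrogen-bond perturbation (bond accepted by the amide group's",
  "own carbonyl oxygen): delta = exp(-k*r)*(a*cos^2(theta_HOC)+b) [ppm].",
  "Synthetic coefficients."))

# 6. Tertiary polarization increments ----------------------------------------
tertiary <- data.frame(
  situation = c("PRIMARY_PARTNER_BONDED", "SECONDARY_PARTNER_BONDED"),
  value = c(0.25, 0.12)
)
wtable(tertiary, "inst/extdata/tertiary_increments_synthetic.tsv", c(
  "Tertiary polarization increments (ppm) added when the primary/secondary",
  "hydrogen-bond partner amide is itself hydrogen bonded. Synthetic values."))

# 7. Trans-hydrogen-bond h3J(NC') closed form ---------------------------------
# J(Hz) = -A * exp(-k*(r_HO - r0)) * cos^2(theta1) * (p*cos^2(theta2) + q)
jc <- data.frame(
  param = c("A", "k", "r0", "p", "q"),
  value = c(0.90, 3.2, 1.76, 0.2, 0.8)
)
wtable(jc, "inst/extdata/jcoupling_synthetic.tsv", c(
  "Trans-hydrogen-bond h3J(NC') closed form:",
  "J = -A*exp(-k*(r_HO-r0))*cos^2(theta1)*(p*cos^2(theta2)+q)  [Hz],",
  "theta1 = N-H...O angle, theta2 = H...O=C angle.",
  "Exponential-decay form; synthetic coefficients on the literature scale."))

cat("parameter files written to inst/extdata/\n")
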