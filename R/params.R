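# Parameter-file loading. All coefficients live in documented plain-text
# tables so the algorithms are testable against any coefficient set; the
# shipped defaults are a synthetic parameterization (see file headers and
# the methods vignette).

read_param_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

read_kv <- function(path) {
  df <- read_param_table(path)
  stats::setNames(df$value, df$param)
}

read_grid <- function(path) {
  df <- read_param_table(path)
  r <- sort(unique(df$r))
  a <- sort(unique(df$angle))
  m <- matrix(NA_real_, length(r), length(a))
  m[cbind(match(df$r, r), match(df$angle, a))] <- df$value
  if (anyNA(m)) stop("incomplete grid in ", path, call. = FALSE)
  list(r = r, angle = a, values = m)
}

#' Load the chemical-shift model parameter set
#'
#' Reads the backbone cosine-series coefficients, ring-current intensities,
#' hydrogen-bond closed forms and lookup grids, tertiary increments and
#' h3J(NC') coupling coefficients from plain-text tables. The shipped
#' defaults (in `system.file("extdata", package = "amideshift")`) are a
#' synthetic parameterization with realistic magnitudes; drop-in replacement
#' files let any coefficient set be used.
#'
#' @param dir Directory holding the parameter tables; defaults to the files
#'   bundled with the package.
#' @param scale Length-2 numeric `c(a, b)`: the backbone term is reported as
#'   `a * series + b` (accounts for basis-set/geometry differences in the
#'   underlying parameterization). Default `c(1, 0)`.
#' @param gate Hydrogen-bond detection gate, see [detect_hbonds()].
#' @return A list of class `shift_params`.
#' @export
shift_params <- function(dir = NULL, scale = c(1, 0),
                         gate = list(r_max = 2.5, nho_min = 120)) {
  if (is.null(dir)) dir <- system.file("extdata", package = "amideshift")
  f <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) {
      stop("configuration error: missing parameter file ", p, call. = FALSE)
    }
    p
  }
  ri <- read_param_table(f("ring_intensities_synthetic.tsv"))
  structure(list(
    backbone = read_param_table(f("backbone_series_synthetic.tsv")),
    scale = scale,
    ring_intensity = stats::setNames(ri$intensity, ri$kind),
    ring_B = 30.42,  # ppm A^3, point-dipole constant
    primary = as.list(read_kv(f("hb_amide_primary_synthetic.tsv"))),
    grids = list(
      CARBOXYLATE = read_grid(f("hb_carboxylate_grid_synthetic.tsv")),
      ALCOHOL = read_grid(f("hb_alcohol_grid_synthetic.tsv"))
    ),
    secondary = as.list(read_kv(f("hb_secondary_synthetic.tsv"))),
    tertiary = {
      tt <- read_param_table(f("tertiary_increments_synthetic.tsv"))
      stats::setNames(tt$value, tt$situation)
    },
    jcoupling = as.list(read_kv(f("jcoupling_synthetic.tsv"))),
    gate = gate
  ), class = "shift_params")
}

#' @export
print.shift_params <- function(x, ...) {
  cat("<shift_params>\n")
  cat("  backbone series terms:", nrow(x$backbone),
      " scale: a =", x$scale[1], "b =", x$scale[2], "\n")
  cat("  ring intensities:",
      paste(names(x$ring_intensity), x$ring_intensity, collapse = ", "), "\n")
  cat("  solvent-exposed primary term:", x$primary$none_value, "ppm\n")
  cat("  H-bond gate: r <=", x$gate$r_max, "A, N-H...O >=", x$gate$nho_min, "deg\n")
  invisible(x)
}

#' Bilinear interpolation on a (r, angle) perturbation grid
#'
#' Exact at grid nodes; out-of-range queries are clamped to the grid boundary
#' with a warning (no extrapolation).
#'
#' @param grid A grid as stored in [shift_params()] (`r`, `angle`, `values`).
#' @param r,angle Query coordinates (vectors, recycled).
#' @return Interpolated perturbations (ppm).
#' @export
interp_surface <- function(grid, r, angle) {
  n <- max(length(r), length(angle))
  r <- rep_len(r, n); angle <- rep_len(angle, n)
  rr <- range(grid$r); ar <- range(grid$angle)
  if (any(r < rr[1] - 1e-9 | r > rr[2] + 1e-9 |
          angle < ar[1] - 1e-9 | angle > ar[2] + 1e-9)) {
    warning("geometry outside surface grid; clamped to boundary", call. = FALSE)
  }
  r <- pmin(pmax(r, rr[1]), rr[2])
  angle <- pmin(pmax(angle, ar[1]), ar[2])
  i <- findInterval(r, grid$r, rightmost.closed = TRUE)
  j <- findInterval(angle, grid$angle, rightmost.closed = TRUE)
  i <- pmin(i, length(grid$r) - 1)
  j <- pmin(j, length(grid$angle) - 1)
  tr <- (r - grid$r[i]) / (grid$r[i + 1] - grid$r[i])
  ta <- (angle - grid$angle[j]) / (grid$angle[j + 1] - grid$angle[j])
  v00 <- grid$values[cbind(i, j)]
  v10 <- grid$values[cbind(i + 1, j)]
  v01 <- grid$values[cbind(i, j + 1)]
  v11 <- grid$values[cbind(i + 1, j + 1)]
  (1 - tr) * (1 - ta) * v00 + tr * (1 - ta) * v10 +
    (1 - tr) * ta * v01 + tr * ta * v11
}

#' Read a YAML configuration file for sigma overrides, gate and move settings
#'
#' Recognised keys: `sigma` (named list of per-class ppm), `gate`
#' (`r_max`, `nho_min`), `scale` (`a`, `b`), `moves` (`backbone_frac`,
#' `sd_backbone`, `sd_sidechain`), `temperature`, `save_every`.
#'
#' @param path YAML file path.
#' @return A named list of settings (possibly empty).
#' @export
read_shift_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) list() else cfg
}
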