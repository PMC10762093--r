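#' Default run configuration for the two-vesicle fusion experiment
#'
#' Returns the full configuration list with the reference setup: two
#' spherical vesicles of diameter 146 nm (bilayer thickness 5 nm, so
#' `eps = 5/6` nm), bending rigidity 20 kBT, baseline Gaussian modulus
#' -20 kBT, zero spontaneous curvature, a modified-modulus patch covering
#' 2% of the total area, a `[0, 96 eps] x [-245 eps, 245 eps]` domain at
#' 144 x 735 cells, and a 100-image string. All lengths are in nm.
#'
#' @return nested list with blocks `grid`, `physics`, `geometry`,
#'   `constraints`, `string` and `output`.
#' @export
default_run_config <- function() {
  eps <- 5 / 6
  list(
    grid = list(nr = 144L, nz = 735L, r_max = 96 * eps,
                z_min = -245 * eps, z_max = 245 * eps),
    physics = list(k = 20, kG0 = -20, m = 0, eps = eps, mobility = 1),
    geometry = list(diameter = 146, gap = 3 * eps,
                    patch_fraction = 0.02),
    constraints = list(M1 = NA_real_, M2 = NA_real_, M3 = NA_real_,
                       M4 = NA_real_),
    string = list(n_images = 100L, n_outer = 2000L, n_inner = 2L,
                  dt = 2e-3, tol = 1e-4),
    output = list(dir = "fusion_out", snapshot_every = 0L)
  )
}

#' Read and validate a run configuration
#'
#' Reads a YAML file whose blocks mirror [default_run_config()]; missing
#' entries fall back to the defaults. Validation rejects non-positive
#' physical quantities and out-of-range patch fractions before any
#' computation.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (blk in names(user)) {
      if (!blk %in% names(cfg)) stop("unknown config block: ", blk)
      for (key in names(user[[blk]])) {
        if (!key %in% names(cfg[[blk]])) {
          stop("unknown config key: ", blk, "$", key)
        }
        cfg[[blk]][[key]] <- user[[blk]][[key]]
      }
    }
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg configuration list to validate.
#' @export
validate_run_config <- function(cfg) {
  with(cfg, {
    if (physics$eps <= 0) stop("invalid config: eps must be positive")
    if (physics$k <= 0) stop("invalid config: k must be positive")
    if (geometry$diameter <= 0) {
      stop("invalid config: diameter must be positive")
    }
    if (geometry$gap < 0) stop("invalid config: gap must be >= 0")
    if (geometry$patch_fraction < 0 || geometry$patch_fraction > 1) {
      stop("invalid config: patch_fraction must be in [0, 1]")
    }
    if (string$n_images < 3) stop("invalid config: n_images must be >= 3")
    if (string$dt <= 0) stop("invalid config: dt must be positive")
  })
  cfg
}

# Short stable hash of a configuration (for log provenance)
.config_hash <- function(cfg) {
  txt <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  # djb2 string hash, hex-coded
  h <- 5381
  for (ch in utf8ToInt(txt)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}
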