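#' Pipeline configuration
#'
#' Collects every tunable parameter of the scoring pipeline with its default
#' operating point. Defaults correspond to the method's canonical operating
#' point: `beta = 0.5` mixes expression/topology similarity against the
#' binary adjacency on known edges; `phi`, `theta`, `tau` weight the
#' subcellular, triangle and orthology feature scores; `omega` mixes the
#' domain-derived score against the combined feature score; `mu` is the
#' damping weight of the score iteration and `rho` the total allocation mass
#' each protein distributes per step.
#'
#' Note that the canonical feature weights `0.25 + 0.35 + 0.45 = 1.05` exceed
#' one; they are used verbatim by default. Set
#' `normalize_feature_weights = TRUE` to rescale them to unit sum.
#'
#' @param beta Mixing weight in `[0, 1]` between the pairwise association
#'   score and the binary adjacency for known interactions.
#' @param phi,theta,tau Nonnegative weights of the subcellular-localization,
#'   triangle and orthology feature scores.
#' @param omega Mixing weight between the domain-derived score and the
#'   combined feature score.
#' @param mu Damping weight in `(0, 1)` of the propagated score against the
#'   initial score in the fixed-point iteration.
#' @param rho Total allocation mass in `(0, 1]` each nonzero row of the
#'   weight-allocation matrix sums to.
#' @param epsilon Positive convergence threshold on the squared Euclidean
#'   norm of successive score differences.
#' @param dft_length Number of spectrum points `N` for the expression DFT;
#'   `NULL` (default) uses the series length `M`. Must satisfy `N >= M`.
#' @param alpha_prime Kernel bandwidth scaling for the expression-spectrum
#'   kernel (unit by convention).
#' @param delta_prime Kernel bandwidth scaling for the domain
#'   annotation-profile kernel (unit by convention).
#' @param normalize_feature_weights If `TRUE`, rescale `phi`, `theta`, `tau`
#'   to sum to one before combining feature scores.
#' @param max_iter Safety cap on score iterations.
#' @param random_seed Optional integer seed recorded in run manifests.
#' @return A `wpdinm_config` list.
#' @export
#' @examples
#' cfg <- pipeline_config(mu = 0.2)
#' cfg$mu
pipeline_config <- function(beta = 0.5, phi = 0.25, theta = 0.35, tau = 0.45,
                            omega = 0.7, mu = 0.4, rho = 0.85,
                            epsilon = 1e-6, dft_length = NULL,
                            alpha_prime = 1, delta_prime = 1,
                            normalize_feature_weights = FALSE,
                            max_iter = 10000L, random_seed = NULL) {
  cfg <- list(beta = beta, phi = phi, theta = theta, tau = tau,
              omega = omega, mu = mu, rho = rho, epsilon = epsilon,
              dft_length = dft_length, alpha_prime = alpha_prime,
              delta_prime = delta_prime,
              normalize_feature_weights = isTRUE(normalize_feature_weights),
              max_iter = as.integer(max_iter), random_seed = random_seed)
  validate_config(cfg)
  structure(cfg, class = "wpdinm_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid configuration: ", msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(cfg$beta) && cfg$beta >= 0 && cfg$beta <= 1, "beta must lie in [0, 1]")
  for (nm in c("phi", "theta", "tau", "omega")) {
    chk(num1(cfg[[nm]]) && cfg[[nm]] >= 0, paste(nm, "must be nonnegative"))
  }
  chk(num1(cfg$omega) && cfg$omega <= 1, "omega must lie in [0, 1]")
  chk(num1(cfg$mu) && cfg$mu > 0 && cfg$mu < 1, "mu must lie in (0, 1)")
  chk(num1(cfg$rho) && cfg$rho > 0 && cfg$rho <= 1, "rho must lie in (0, 1]")
  chk(num1(cfg$epsilon) && cfg$epsilon > 0, "epsilon must be positive")
  chk(num1(cfg$alpha_prime) && cfg$alpha_prime > 0, "alpha_prime must be positive")
  chk(num1(cfg$delta_prime) && cfg$delta_prime > 0, "delta_prime must be positive")
  chk(is.null(cfg$dft_length) ||
        (num1(cfg$dft_length) && cfg$dft_length >= 1), "dft_length must be >= 1")
  chk(num1(cfg$max_iter) && cfg$max_iter >= 1, "max_iter must be >= 1")
  invisible(cfg)
}

#' Read a configuration file
#'
#' Accepts either a YAML mapping or flat `key=value` lines; keys mirror the
#' arguments of [pipeline_config()]. Unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @param base Configuration whose values the file overrides.
#' @return A `wpdinm_config` list.
#' @export
read_config_file <- function(path, base = pipeline_config()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt)) & !grepl("^\\s*#", txt)]
  if (length(txt) && all(grepl("=", txt, fixed = TRUE))) {
    kv <- strsplit(txt, "=", fixed = TRUE)
    vals <- lapply(kv, function(p) utils::type.convert(trimws(paste(p[-1], collapse = "=")),
                                                       as.is = TRUE))
    names(vals) <- vapply(kv, function(p) trimws(p[[1]]), character(1))
  } else {
    vals <- yaml::read_yaml(path)
  }
  unknown <- setdiff(names(vals), names(unclass(base)))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- unclass(base)
  cfg[names(vals)] <- vals
  do.call(pipeline_config, cfg)
}
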