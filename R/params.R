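#' Rate and affinity parameters of the dual-feedback oscillator
#'
#' Constructs the parameter set of the four-variable delay model of the
#' oscillator (LacI repressor `r`, AraC activator `a`, immature GFP `g`,
#' mature GFP `G`).  Defaults are the fitted values for growth in 2 mM IPTG.
#' The three maximal production rates are tied to the per-plasmid rate
#' `alpha` through the plasmid copy numbers and protein multimericity:
#' `alpha_g = 60 alpha` (monomer on the 60-copy reporter plasmid),
#' `alpha_a = 60 alpha / 2` (dimer), `alpha_r = 25 alpha / 4` (tetramer on
#' the 25-copy repressor plasmid).  Supplying `alpha_r`, `alpha_a` or
#' `alpha_g` directly overrides the tie (used for per-cell heritable rates).
#'
#' @param alpha Maximal per-plasmid production rate when fully induced,
#'   molecules cell^-1 min^-1.
#' @param gamma_r,gamma_a,gamma_g Maximal ClpXP proteolysis rates,
#'   molecules cell^-1 min^-1.
#' @param gamma_G Proteolysis rate of mature GFP; defaults to `gamma_g`
#'   (mature and immature GFP carry the same degradation tag).
#' @param R0 Michaelis constant of the shared proteolysis machinery,
#'   molecules cell^-1.
#' @param C_a,C_r Concentrations for half-maximal induction / repression,
#'   molecules cell^-1.
#' @param f Activation strength relative to basal production (unitless).
#' @param tau_r,tau_a,tau_g Transcriptional delays, min.
#' @param lambda_mat GFP maturation rate, min^-1 (10-min half-time).
#' @param beta Dilution rate due to cell growth, min^-1.
#' @param alpha_r,alpha_a,alpha_g Optional direct production rates,
#'   molecules cell^-1 min^-1.
#' @return An object of class `oscillator_params` (named list).
#' @examples
#' p <- oscillator_params()
#' p$alpha_g / p$alpha  # 60 copies of the reporter plasmid
#' @export
oscillator_params <- function(alpha = 10, gamma_r = 8, gamma_a = 24,
                              gamma_g = 48, gamma_G = NULL, R0 = 0.0456,
                              C_a = 0.791, C_r = 3.36, f = 17,
                              tau_r = 6, tau_a = 5.5, tau_g = 5,
                              lambda_mat = log(2) / 10, beta = 0.0295,
                              alpha_r = NULL, alpha_a = NULL,
                              alpha_g = NULL) {
  p <- list(
    alpha = alpha,
    alpha_r = if (is.null(alpha_r)) 25 * alpha / 4 else alpha_r,
    alpha_a = if (is.null(alpha_a)) 60 * alpha / 2 else alpha_a,
    alpha_g = if (is.null(alpha_g)) 60 * alpha else alpha_g,
    gamma_r = gamma_r, gamma_a = gamma_a, gamma_g = gamma_g,
    gamma_G = if (is.null(gamma_G)) gamma_g else gamma_G,
    R0 = R0, C_a = C_a, C_r = C_r, f = f,
    tau_r = tau_r, tau_a = tau_a, tau_g = tau_g,
    lambda_mat = lambda_mat, beta = beta
  )
  class(p) <- "oscillator_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  for (nm in c("R0", "C_a", "C_r", "f", "lambda_mat", "beta")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a single positive number")
  }
  # production / proteolysis rates may be exactly zero (knockouts)
  for (nm in c("alpha", "alpha_r", "alpha_a", "alpha_g", "gamma_r",
               "gamma_a", "gamma_g", "gamma_G")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] < 0)
      stop("parameter '", nm, "' must be a single nonnegative number")
  }
  for (nm in c("tau_r", "tau_a", "tau_g")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] < 0)
      stop("delay '", nm, "' must be a single nonnegative number")
  }
  invisible(p)
}

#' @export
print.oscillator_params <- function(x, ...) {
  cat("Oscillator parameters (molecules/cell, min):\n")
  v <- unlist(x)
  print(round(v, 4))
  invisible(x)
}

#' Promoter activity of the hybrid lac/ara promoter
#'
#' Composite Hill function giving the transcriptional activity as a function
#' of repressor and activator concentrations:
#' `h(r, a) = (1/f + a/C_a) / ((1 + a/C_a) (1 + r/C_r)^2)`.
#' The value is `1/f` at zero induction and saturates at 1 for full
#' activation (`a` large) in the absence of repressor.
#'
#' @param r,a Repressor / activator concentrations, molecules cell^-1
#'   (vectorized).
#' @param f Activation strength (unitless), > 0.
#' @param C_a,C_r Half-maximal induction / repression concentrations.
#' @return Promoter activity in (0, 1], dimensionless.
#' @examples
#' hill_activity(0, 0)        # basal activity 1/f
#' hill_activity(0, 1e9)      # full activation -> 1
#' @export
hill_activity <- function(r, a, f = 17, C_a = 0.791, C_r = 3.36) {
  if (any(r < 0) || any(a < 0))
    stop("concentrations must be nonnegative")
  if (f <= 0 || C_a <= 0 || C_r <= 0)
    stop("f, C_a and C_r must be positive")
  (1 / f + a / C_a) / ((1 + a / C_a) * (1 + r / C_r)^2)
}

#' Molecule-number scaling family of the oscillator parameters
#'
#' Rescales the parameter set so that deterministic concentration dynamics
#' are unchanged while absolute molecule numbers are multiplied by `omega`:
#' production rates, proteolysis rates and the affinity constants `R0`,
#' `C_a`, `C_r` are multiplied by `omega`; `f`, the delays, the maturation
#' rate and the dilution rate are untouched.  In stochastic simulations
#' `omega` therefore sets the intrinsic-noise level (larger `omega`, more
#' molecules, less noise).
#'
#' @param params An [oscillator_params()] object.
#' @param omega Positive scaling factor.
#' @return The rescaled `oscillator_params`.
#' @export
rescale_params <- function(params, omega) {
  stopifnot(inherits(params, "oscillator_params"))
  if (!is.numeric(omega) || length(omega) != 1 || !is.finite(omega) ||
      omega <= 0)
    stop("omega must be a single positive number")
  p <- params
  for (nm in c("alpha", "alpha_r", "alpha_a", "alpha_g", "gamma_r",
               "gamma_a", "gamma_g", "gamma_G", "R0", "C_a", "C_r"))
    p[[nm]] <- p[[nm]] * omega
  validate_params(p)
  p
}

#' Read / write oscillator parameters as flat JSON
#'
#' Parameter sets are stored as a flat key-value JSON object using the field
#' names of [oscillator_params()].
#'
#' @param path File path.
#' @param params An `oscillator_params` object.
#' @return `read_params()` returns an `oscillator_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- oscillator_params(
    alpha = v$alpha, gamma_r = v$gamma_r, gamma_a = v$gamma_a,
    gamma_g = v$gamma_g, gamma_G = v$gamma_G, R0 = v$R0, C_a = v$C_a,
    C_r = v$C_r, f = v$f, tau_r = v$tau_r, tau_a = v$tau_a, tau_g = v$tau_g,
    lambda_mat = v$lambda_mat, beta = v$beta, alpha_r = v$alpha_r,
    alpha_a = v$alpha_a, alpha_g = v$alpha_g
  )
  p
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "oscillator_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# internal: flatten to the vector layout shared with the C++ kernels
param_vector <- function(p) {
  c(p$alpha_r, p$alpha_a, p$alpha_g, p$gamma_r, p$gamma_a, p$gamma_g,
    p$gamma_G, p$R0, p$C_a, p$C_r, p$f, p$tau_r, p$tau_a, p$tau_g,
    p$lambda_mat, p$beta)
}
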