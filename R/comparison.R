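## Head-to-head comparison of the two mechanisms: the precision ratio
## rho_j = P^2_DT / P^2_SDC at the DT-optimal shape, the fraction of cells
## for which SDC wins, and the crossover lengthscale lambda_hat_50.

#' DT-to-SDC precision ratio across a line of cells
#'
#' For each cell pair \eqn{j}, computes
#' \eqn{\rho_j = P^2_{DT}(\phi^*_j)/P^2_{SDC}} at matched \eqn{N},
#' \eqn{j}, \eqn{\beta}, \eqn{T} and profile lengthscale
#' \eqn{\hat\lambda}, optimising the DT shape \eqn{\phi} per cell.
#' \eqn{\beta}, \eqn{T} and \eqn{\nu} cancel from the ratio, so they are
#' fixed to 1 internally. \eqn{\rho_j > 1} means direct transport reads
#' out more precisely at cell \eqn{j}; short profiles favour DT (larger
#' amplitude), long profiles favour SDC (faster refresh by diffusion).
#'
#' @param N Cells per side (>= 2).
#' @param lambda_hat Profile lengthscale in cell radii.
#' @param dim Dimensionality (1, 2 or 3); the DT side is unaffected
#'   (cytonemes extend perpendicular to the source), the SDC variance for
#'   `dim > 1` comes from [precision_sdc_nd()].
#' @param j Cell indices to evaluate (default all of `1:(N-1)`).
#' @param nd_control Lattice controls for `dim > 1`, see
#'   [precision_sdc_nd()].
#' @return Object of class `ms_comparison`: list with `lambda_hat`,
#'   `dim`, `j`, `rho`, `phi_star`, `fraction_sdc`.
#' @export
precision_ratio <- function(N, lambda_hat, dim = 1L, j = NULL,
                            nd_control = list()) {
  stopifnot(N >= 2, lambda_hat > 0, dim %in% 1:3)
  if (is.null(j)) j <- seq_len(N - 1)
  opt <- .dt_opt_phi(N, lambda_hat, j_set = j, warn_boundary = FALSE)
  p2dt <- opt$p_squared_star
  params <- sdc_params(beta = 1, D = lambda_hat^2, nu = 1, a = 1, dim = dim)
  if (dim == 1L) {
    ## closed form at beta = T = nu = 1; cells beyond ~350 lengthscales
    ## underflow to zero mean and count as DT-favoured (rho infinite)
    m <- mean_profile_sdc(params, N)
    p2sdc <- m[j] * (1 - exp(-2 / lambda_hat))^2 /
      (2 * correlation_time_sdc(lambda_hat, 1))
  } else {
    p2sdc <- precision_sdc_nd(params, N, T = 100, j = j,
                              control = nd_control)$p_squared / 100
  }
  rho <- p2dt / p2sdc
  structure(list(lambda_hat = lambda_hat, dim = dim, j = j, rho = rho,
                 phi_star = opt$phi_star,
                 fraction_sdc = mean(rho <= 1)),
            class = "ms_comparison")
}

#' @export
print.ms_comparison <- function(x, ...) {
  cat(sprintf(paste0("DT vs SDC at lambda_hat = %g (%dD): rho in ",
                     "[%.3g, %.3g], fraction of cells favouring SDC = %.3f\n"),
              x$lambda_hat, x$dim, min(x$rho), max(x$rho), x$fraction_sdc))
  invisible(x)
}

#' Fraction of cells for which SDC is the more precise mechanism
#'
#' The fraction of cell pairs \eqn{j \in 1..N-1} with \eqn{\rho_j \le 1}
#' (exact ties, a measure-zero event, are counted toward SDC).
#'
#' @inheritParams precision_ratio
#' @return A number in \eqn{[0, 1]}.
#' @export
fraction_sdc_better <- function(N, lambda_hat, dim = 1L,
                                nd_control = list()) {
  precision_ratio(N, lambda_hat, dim = dim,
                  nd_control = nd_control)$fraction_sdc
}

## cache for the (deterministic, moderately expensive) crossover solves
.ms_cache <- new.env(parent = emptyenv())

#' Crossover lengthscale at which half the cells favour SDC
#'
#' The smallest \eqn{\hat\lambda} at which
#' [fraction_sdc_better()] reaches 0.5, located by bracketing on a log
#' grid over \eqn{[0.1, 10^3]} followed by bisection to a relative
#' tolerance of 1e-3. Morphogen systems with \eqn{\hat\lambda} below this
#' value are predicted to gain precision from direct transport, above it
#' from diffusion. The fraction is quantised in steps of \eqn{1/(N-1)},
#' so the value at the crossover lies within one step of 0.5. Results are
#' cached per `(N, dim)`.
#'
#' @param N Cells per side (>= 3).
#' @param dim Dimensionality (default 1; the classification of real
#'   morphogens uses 1D, which higher dimensions change little).
#' @param nd_control Lattice controls for `dim > 1`.
#' @return The crossover lengthscale \eqn{\hat\lambda_{50}}.
#' @export
lambda50 <- function(N, dim = 1L, nd_control = list()) {
  stopifnot(N >= 3)
  key <- sprintf("l50_%d_%d", as.integer(N), as.integer(dim))
  if (!is.null(.ms_cache[[key]])) return(.ms_cache[[key]])
  f <- function(lh) fraction_sdc_better(N, lh, dim = dim,
                                        nd_control = nd_control)
  grid <- exp(seq(log(0.1), log(1000), length.out = 15))
  fr <- vapply(grid, f, numeric(1))
  ix <- which(fr >= 0.5)
  if (!length(ix) || ix[1] == 1L) {
    stop("no 50% crossover found in lambda_hat = [0.1, 1000]; fractions: ",
         paste(sprintf("%.2f", fr), collapse = " "))
  }
  hi <- grid[ix[1]]; lo <- grid[ix[1] - 1]
  while ((hi - lo) / hi > 1e-3) {
    mid <- sqrt(lo * hi)
    if (f(mid) >= 0.5) hi <- mid else lo <- mid
  }
  .ms_cache[[key]] <- hi
  hi
}

## smallest lambda_hat with fraction >= q (used for figure contours)
.lambda_at_fraction <- function(N, q, dim = 1L) {
  f <- function(lh) fraction_sdc_better(N, lh, dim = dim)
  grid <- exp(seq(log(0.1), log(1000), length.out = 15))
  fr <- vapply(grid, f, numeric(1))
  ix <- which(fr >= q)
  if (!length(ix) || ix[1] == 1L) return(NA_real_)
  hi <- grid[ix[1]]; lo <- grid[ix[1] - 1]
  while ((hi - lo) / hi > 1e-3) {
    mid <- sqrt(lo * hi)
    if (f(mid) >= q) hi <- mid else lo <- mid
  }
  hi
}

#' Classify morphogens by predicted gradient-formation mechanism
#'
#' Annotates each morphogen record with its dimensionless lengthscale
#' \eqn{\hat\lambda = \lambda/a}, the crossover \eqn{\hat\lambda_{50}}
#' for its own cell count \eqn{N}, their ratio, the fraction of cells
#' for which SDC is predicted to be more precise, and the predicted
#' mechanism (SDC when that fraction exceeds 0.5, otherwise DT). The
#' summary reports concordance between prediction and the experimental
#' `evidence_class`; records with `evidence_class = "multiple"` are
#' excluded from the concordance count.
#'
#' @param records A data frame as returned by [load_morphogen_table()]
#'   (columns `name`, `species`, `lambda_um`, `a_um`, `N`,
#'   `evidence_class`, optionally `provenance_note`).
#' @param dim Dimensionality used for the theory (default 1).
#' @return List with `records` (annotated data frame) and `summary`
#'   (list: `n`, `n_classified`, `n_concordant`, `concordance`). If any
#'   record's provenance is not literature-verified, the summary's
#'   `verified` flag is `FALSE` and concordance should not be read as a
#'   test of the theory.
#' @export
classify_morphogens <- function(records, dim = 1L) {
  records <- .validate_morphogen_records(records)
  records$lambda_hat <- records$lambda_um / records$a_um
  l50 <- vapply(records$N, function(n) lambda50(n, dim = dim), numeric(1))
  records$lambda50 <- l50
  records$lambda_hat_over_lambda50 <- records$lambda_hat / l50
  records$fraction_sdc_better <- mapply(
    function(n, lh) fraction_sdc_better(n, lh, dim = dim),
    records$N, records$lambda_hat)
  records$predicted <- ifelse(records$fraction_sdc_better > 0.5, "SDC", "DT")
  cls <- records$evidence_class != "multiple"
  n_conc <- sum(records$predicted[cls] == records$evidence_class[cls])
  verified <- if ("provenance_note" %in% names(records))
    !any(grepl("unverified", records$provenance_note, ignore.case = TRUE))
  else FALSE
  if (!verified)
    message("morphogen table contains unverified placeholder values; ",
            "concordance is illustrative only")
  list(records = records,
       summary = list(n = nrow(records), n_classified = sum(cls),
                      n_concordant = n_conc,
                      concordance = if (sum(cls)) n_conc / sum(cls) else NA,
                      verified = verified))
}
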