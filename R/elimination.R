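vk_powers <- c(kinetic = 0, diffusion = 0.5, capacitive = 1)

#' Specify an elimination function
#'
#' Elimination voltammetry removes current components with known scan-rate
#' power laws by linearly combining voltammograms recorded at different scan
#' rates. The components scale as v^0 (kinetic), v^(1/2) (diffusion) and v^1
#' (capacitive). One component is conserved (its combined amplitude stays 1
#' at the reference rate) and one or two are eliminated; eliminating one
#' component needs two scan rates, eliminating two needs three.
#'
#' @param conserve The conserved component: `"kinetic"`, `"diffusion"` or
#'   `"capacitive"`.
#' @param eliminate Character vector of 0-2 components to cancel, disjoint
#'   from `conserve`.
#' @param rel_rates Relative scan rates `v_i / v_ref`, pairwise distinct,
#'   exactly one equal to 1; length must be `length(eliminate) + 1`.
#' @param label Optional tag (e.g. `"E4"`).
#' @return A list of class `elimination_spec`.
#' @export
#' @examples
#' elimination_spec("diffusion", c("kinetic", "capacitive"), c(0.5, 1, 2))
elimination_spec <- function(conserve, eliminate = character(),
                             rel_rates, label = NULL) {
  conserve <- match.arg(conserve, names(vk_powers))
  eliminate <- vapply(eliminate, match.arg, "", choices = names(vk_powers),
                      USE.NAMES = FALSE)
  if (conserve %in% eliminate) {
    vk_abort("invalid_spec", "The conserved component cannot also be eliminated.")
  }
  if (anyDuplicated(eliminate)) {
    vk_abort("invalid_spec", "Eliminated components must be distinct.")
  }
  rel_rates <- as.numeric(rel_rates)
  if (length(rel_rates) != length(eliminate) + 1L) {
    vk_abort("invalid_spec", sprintf(
      "Eliminating %d component(s) needs %d scan rates, got %d.",
      length(eliminate), length(eliminate) + 1L, length(rel_rates)))
  }
  if (any(rel_rates <= 0)) vk_abort("invalid_spec", "Relative rates must be > 0.")
  if (anyDuplicated(rel_rates)) {
    vk_abort("singular_system", "Repeated relative rates make the system singular.")
  }
  if (sum(abs(rel_rates - 1) < 1e-12) != 1L) {
    vk_abort("invalid_spec", "Exactly one relative rate must equal 1 (the reference).")
  }
  structure(list(conserve = conserve, eliminate = eliminate,
                 rel_rates = rel_rates, label = label),
            class = "elimination_spec")
}

#' @export
print.elimination_spec <- function(x, ...) {
  cat(sprintf("<elimination_spec%s> conserve %s%s | rel. rates %s\n",
              if (!is.null(x$label)) paste0(" ", x$label) else "",
              x$conserve,
              if (length(x$eliminate)) paste0(", eliminate ",
                                              paste(x$eliminate, collapse = "+")) else "",
              paste(x$rel_rates, collapse = ", ")))
  invisible(x)
}

#' Solve for elimination coefficients
#'
#' Builds and solves the square linear system `sum_i a_i * rho_i^p = b_p`
#' over the powers p of the conserved and eliminated components, with
#' right-hand side 1 for the conserved power and 0 for each eliminated one.
#'
#' @param spec An [elimination_spec()] (or arguments forwarded to it).
#' @param ... Forwarded to [elimination_spec()] when `spec` is a component
#'   name.
#' @return An object of class `elimination_fit` with elements
#'   `coefficients` (named by relative rate), `spec` and `residuals`.
#' @export
#' @examples
#' fit <- solve_elimination(elimination_spec("diffusion",
#'                          c("kinetic", "capacitive"), c(0.5, 1, 2)))
#' coef(fit)
solve_elimination <- function(spec, ...) {
  if (!inherits(spec, "elimination_spec")) spec <- elimination_spec(spec, ...)
  powers <- unname(vk_powers[c(spec$conserve, spec$eliminate)])
  A <- t(vapply(powers, function(p) spec$rel_rates^p,
                numeric(length(spec$rel_rates))))
  b <- c(1, rep(0, length(spec$eliminate)))
  a <- tryCatch(solve(A, b), error = function(e)
    vk_abort("singular_system", "The elimination system is singular."))
  structure(list(coefficients = setNames(a, paste0("rho=", spec$rel_rates)),
                 spec = spec,
                 residuals = drop(A %*% a) - b),
            class = "elimination_fit")
}

#' @export
coef.elimination_fit <- function(object, ...) object$coefficients

#' @export
print.elimination_fit <- function(x, ...) {
  print(x$spec)
  cat("coefficients:\n")
  print(signif(x$coefficients, 6))
  invisible(x)
}

#' Tidy an elimination fit
#'
#' @param x An `elimination_fit`.
#' @param ... Unused.
#' @return One row per input voltammogram: relative rate and coefficient.
#' @method tidy elimination_fit
#' @export
tidy.elimination_fit <- function(x, ...) {
  tibble(rel_rate = x$spec$rel_rates,
         coefficient = unname(x$coefficients))
}

#' @rdname tidy.elimination_fit
#' @return `glance()`: a one-row summary with the conserved/eliminated
#'   components and the maximum constraint residual.
#' @method glance elimination_fit
#' @export
glance.elimination_fit <- function(x, ...) {
  tibble(label = x$spec$label %||% NA_character_,
         conserve = x$spec$conserve,
         eliminate = paste(x$spec$eliminate, collapse = "+"),
         n_rates = length(x$spec$rel_rates),
         max_residual = max(abs(x$residuals)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply an elimination function to a voltammogram set
#'
#' Forms `f(I)(E) = sum_i a_i I_i(E)` on the reference voltammogram's
#' potential grid. The voltammograms must carry scan rates (or `rates` must
#' be given) matching the spec's relative rates up to a common reference.
#' Inputs whose potential grids differ from the reference are linearly
#' interpolated onto it (monotone records only); points outside any input's
#' range are dropped, never extrapolated.
#'
#' @param vgrams List of `voltammogram`s, one per relative rate.
#' @param spec An [elimination_spec()] or `elimination_fit`.
#' @param rates Absolute scan rates (V s^-1) overriding the attached ones.
#' @return The eliminated `voltammogram` at the reference scan rate, with
#'   the fit in attribute `elimination`.
#' @export
apply_elimination <- function(vgrams, spec, rates = NULL) {
  fit <- if (inherits(spec, "elimination_fit")) spec else solve_elimination(spec)
  spec <- fit$spec
  if (is.null(rates)) {
    rates <- vapply(vgrams, function(v) scan_rate(v) %||% NA_real_, numeric(1))
  }
  if (length(vgrams) != length(spec$rel_rates) || anyNA(rates)) {
    vk_abort("rate_mismatch", sprintf(
      "Need %d voltammograms with scan rates (got %d).",
      length(spec$rel_rates), length(vgrams)))
  }
  ord <- match_rates(rates, spec$rel_rates)
  vgrams <- vgrams[ord]
  rates <- rates[ord]
  ref <- vgrams[[which(abs(spec$rel_rates - 1) < 1e-12)]]
  grid <- ref$potential
  same_grid <- all(vapply(vgrams, function(v)
    nrow(v) == length(grid) && max(abs(v$potential - grid)) <= 1e-9, logical(1)))
  if (same_grid) {
    ys <- vapply(vgrams, function(v) v$current, numeric(length(grid)))
    keep <- rep(TRUE, length(grid))
  } else {
    if (any(vapply(vgrams, function(v) is.unsorted(v$potential) &&
                   is.unsorted(rev(v$potential)), logical(1)))) {
      vk_abort("grid_mismatch",
               "Grids differ and at least one record is non-monotone; re-grid or split cycles first.")
    }
    ys <- vapply(vgrams, function(v)
      interp_lin(v$potential, v$current, grid),
      numeric(length(grid)))
    keep <- rowSums(is.na(ys)) == 0L
    if (!any(keep)) vk_abort("grid_mismatch", "No common potential range.")
  }
  f <- drop(ys %*% unname(fit$coefficients))
  out <- voltammogram(grid[keep], f[keep], scan_rate = scan_rate(ref),
                      iupac = attr(ref, "iupac"),
                      label = paste0("elimination ", spec$label %||%
                                       paste0("conserve-", spec$conserve)))
  attr(out, "elimination") <- fit
  out
}

# order of supplied absolute rates matching spec relative rates; error if none
match_rates <- function(rates, rel_rates, rtol = 1e-6) {
  for (r in rates) {
    rel <- rates / r
    ord <- vapply(rel_rates, function(target) {
      hit <- which(abs(rel - target) <= rtol * target)
      if (length(hit) == 1L) hit else NA_integer_
    }, integer(1))
    if (!anyNA(ord) && !anyDuplicated(ord)) return(ord)
  }
  vk_abort("rate_mismatch", sprintf(
    "Supplied scan rates (%s) do not match the spec's relative rates (%s).",
    paste(signif(rates, 4), collapse = ", "),
    paste(rel_rates, collapse = ", ")))
}

#' The six standard elimination functions
#'
#' For three distinct relative scan rates, returns the six classical
#' conserve/eliminate selections with solved coefficients: E1-E3 are the
#' two-rate single eliminations (conserve diffusion / eliminate capacitive,
#' conserve diffusion / eliminate kinetic, conserve kinetic / eliminate
#' capacitive), built from the reference rate and the smallest other rate;
#' E4-E6 are the three-rate double eliminations conserving diffusion, kinetic
#' and capacitive respectively. The labels are cosmetic; the
#' conserve/eliminate sets are the interface.
#'
#' @param rel_rates Three distinct relative scan rates, one equal to 1.
#' @return Named list (`E1`-`E6`) of `elimination_fit` objects.
#' @export
#' @examples
#' fits <- standard_eliminations(c(0.5, 1, 2))
#' coef(fits$E4)
standard_eliminations <- function(rel_rates = c(0.5, 1, 2)) {
  rel_rates <- as.numeric(rel_rates)
  if (length(rel_rates) != 3L || anyDuplicated(rel_rates)) {
    vk_abort("invalid_spec", "Need 3 distinct relative rates.")
  }
  others <- sort(rel_rates[abs(rel_rates - 1) >= 1e-12])
  pair <- sort(c(1, others[1]))
  specs <- list(
    E1 = elimination_spec("diffusion", "capacitive", pair, label = "E1"),
    E2 = elimination_spec("diffusion", "kinetic", pair, label = "E2"),
    E3 = elimination_spec("kinetic", "capacitive", pair, label = "E3"),
    E4 = elimination_spec("diffusion", c("kinetic", "capacitive"), rel_rates, label = "E4"),
    E5 = elimination_spec("kinetic", c("diffusion", "capacitive"), rel_rates, label = "E5"),
    E6 = elimination_spec("capacitive", c("kinetic", "diffusion"), rel_rates, label = "E6"))
  lapply(specs, solve_elimination)
}
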