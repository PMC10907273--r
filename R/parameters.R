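#' Kinetic rate parameters for the PGK1 model
#'
#' Constructs the full set of mass-action rate constants used by the network.
#' The defaults are the published stopped-flow constants for yeast PGK1
#' substrate binding (pairs `a`--`d`), an assumed symmetric phosphotransfer
#' rate of 5 per second, and a dimensionless terazosin association multiplier
#' `eta` that scales terazosin's on-rates relative to the corresponding
#' nucleotide edges.
#'
#' Pairs `a`--`d` cover the random-order binding diamond: `a` is nucleotide
#' (ADP/ATP) binding to free enzyme, `c` is phosphoglycerate (1,3-BPG/3-PG)
#' binding to free enzyme, `b` is phosphoglycerate binding to a
#' nucleotide-occupied enzyme, and `d` is nucleotide binding to a
#' phosphoglycerate-occupied enzyme. Association constants (`*_plus`) are in
#' per micromolar per second; dissociation constants (`*_minus`) and the
#' phosphotransfer constants (`k_plus`, `k_minus`) are in per second.
#'
#' @param a_plus,a_minus Nucleotide binding to / release from free enzyme.
#' @param b_plus,b_minus Phosphoglycerate binding to a nucleotide- (or
#'   terazosin-) occupied enzyme, and its release.
#' @param c_plus,c_minus Phosphoglycerate binding to / release from free
#'   enzyme. The small default `c_minus` (14 per second) is the slow
#'   3-phosphoglycerate release step that the terazosin bypass circumvents.
#' @param d_plus,d_minus Nucleotide binding to a phosphoglycerate-occupied
#'   enzyme, and its release.
#' @param k_plus,k_minus Forward and reverse phosphotransfer between the two
#'   ternary complexes.
#' @param eta Dimensionless multiplier applied to terazosin association
#'   rate constants (default 562, chosen so that nanomolar terazosin competes
#'   with millimolar ADP).
#'
#' @return A `rate_parameters` object (a validated named list).
#' @examples
#' rate_parameters()
#' rate_parameters(c_minus = 1.6) # a c-/b- ratio of 0.01
#' @export
rate_parameters <- function(a_plus = 6.1, a_minus = 38,
                            b_plus = 170, b_minus = 160,
                            c_plus = 450, c_minus = 14,
                            d_plus = 4.1, d_minus = 270,
                            k_plus = 5, k_minus = 5,
                            eta = 562) {
  p <- list(
    a_plus = a_plus, a_minus = a_minus,
    b_plus = b_plus, b_minus = b_minus,
    c_plus = c_plus, c_minus = c_minus,
    d_plus = d_plus, d_minus = d_minus,
    k_plus = k_plus, k_minus = k_minus,
    eta = eta
  )
  validate_rate_parameters(p)
  structure(p, class = "rate_parameters")
}

validate_rate_parameters <- function(p) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("rate parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    }
    if (v < 0) {
      stop("rate parameter '", nm, "' must be non-negative (got ", v, ")",
           call. = FALSE)
    }
  }
  invisible(p)
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("<rate_parameters>\n")
  pairs <- c("a", "b", "c", "d", "k")
  for (p in pairs) {
    cat(sprintf("  %s+ = %-8g %s- = %g\n", p, x[[paste0(p, "_plus")]],
                p, x[[paste0(p, "_minus")]]))
  }
  cat(sprintf("  eta = %g (terazosin association multiplier)\n", x$eta))
  invisible(x)
}

#' @export
as.data.frame.rate_parameters <- function(x, ...) {
  as.data.frame(tibble::as_tibble(unclass(x)))
}

# Replace a subset of rate parameters, revalidating.
update_rate_parameters <- function(params, replacements) {
  stopifnot(inherits(params, "rate_parameters"))
  bad <- setdiff(names(replacements), names(params))
  if (length(bad)) {
    stop("unknown rate parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p <- unclass(params)
  p[names(replacements)] <- replacements
  do.call(rate_parameters, p)
}
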