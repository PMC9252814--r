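#' Model pKa tables for ionizable groups
#'
#' A `pka_table` holds the intrinsic (model) pKa of each ionizable side chain
#' and of the two terminal groups, together with the polarity (acidic or
#' basic) of each group.  It drives the sequence-mode Henderson-Hasselbalch
#' charge calculation and serves as the environment-free pKa provider for
#' structure mode.
#'
#' @param side_chain named numeric vector of side-chain pKa values; names are
#'   one-letter codes and must cover exactly `D, E, C, Y, H, K, R`.
#' @param n_terminus pKa of the free alpha-amino group.
#' @param c_terminus pKa of the free alpha-carboxyl group.
#' @return An object of class `pka_table` with components `side_chain`,
#'   `n_terminus`, `c_terminus` and `polarity`.
#' @examples
#' tab <- default_pka_table()
#' tab$side_chain[["H"]]
#' @export
pka_table <- function(side_chain, n_terminus = 8.0, c_terminus = 3.2) {
  required <- c("D", "E", "C", "Y", "H", "K", "R")
  if (!is.numeric(side_chain) || !setequal(names(side_chain), required))
    stop("side_chain must be a named numeric vector covering exactly ",
         paste(required, collapse = ", "))
  side_chain <- side_chain[required]
  vals <- c(side_chain, n_terminus, c_terminus)
  if (any(!is.finite(vals)) || any(vals <= 0) || any(vals >= 14))
    stop("all pKa values must lie in the open interval (0, 14)")
  obj <- list(
    side_chain = side_chain,
    n_terminus = n_terminus,
    c_terminus = c_terminus,
    polarity = c(D = "acidic", E = "acidic", C = "acidic", Y = "acidic",
                 H = "basic", K = "basic", R = "basic",
                 n_term = "basic", c_term = "acidic")
  )
  class(obj) <- "pka_table"
  obj
}

#' @rdname pka_table
#' @details The default values are the model pKa constants used by the
#'   PROPKA3 empirical predictor (Asp 3.80, Glu 4.50, His 6.50, Cys 9.00,
#'   Tyr 10.00, Lys 10.50, Arg 12.50, N-terminus 8.00, C-terminus 3.20), so
#'   that sequence mode and structure mode agree when no structural
#'   environment information is available.
#' @export
default_pka_table <- function() {
  pka_table(
    side_chain = c(D = 3.80, E = 4.50, C = 9.00, Y = 10.00,
                   H = 6.50, K = 10.50, R = 12.50),
    n_terminus = 8.00,
    c_terminus = 3.20
  )
}

#' @export
print.pka_table <- function(x, ...) {
  cat("Model pKa table\n")
  cat("  side chains:",
      paste(sprintf("%s=%.2f", names(x$side_chain), x$side_chain),
            collapse = "  "), "\n")
  cat(sprintf("  N-terminus: %.2f   C-terminus: %.2f\n",
              x$n_terminus, x$c_terminus))
  invisible(x)
}

# one-letter codes of the 20 standard amino acids
STANDARD_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# accepted non-standard/ambiguity codes, treated as non-ionizable by default
NONSTANDARD_AA <- c("X", "B", "Z", "U", "O", "J")
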