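#' Discrete protonation states at a given pH
#'
#' Converts per-group pKa values into discrete protonation states: a group
#' is protonated if and only if `pH < pKa` (the tie at `pH == pKa` counts as
#' deprotonated, which makes the set of pH pairs that shift a group exactly
#' the half-open interval rule of [shifting_residues]).  Formal charges
#' follow group polarity: protonated acids
#' are neutral, deprotonated acids carry -1; protonated bases carry +1,
#' deprotonated bases are neutral.  Hydrogen-bond donor/acceptor capability
#' and the aromatic status of the histidine ring are derived per group:
#' a protonated His has both imidazole nitrogens as donors and its ring acts
#' as a cation rather than a pi system; a neutral His is tautomer-agnostic
#' (either ring nitrogen may donate or accept); a protonated carboxylate
#' gains an OH donor while a deprotonated one is acceptor-only.
#'
#' @param pkas a `pka_set`.
#' @param pH pH value in (0, 14).
#' @return A data frame of class `protonation` with the `pka_set` keys plus
#'   `formal_charge`, `protonated`, `donor_capable`, `acceptor_capable`,
#'   `aromatic_ring_neutral` (NA for non-His groups); attribute `pH`.
#' @export
assign_states <- function(pkas, pH) {
  if (pH <= 0 || pH > 14) stop("pH must lie in (0, 14]")
  st <- as.data.frame(pkas)
  pol <- ifelse(st$group == "side_chain",
                GROUP_POLARITY[unname(AA3TO1[st$resid])],
                GROUP_POLARITY[st$group])
  st$polarity <- unname(pol)
  st$protonated <- pH < st$pka
  st$formal_charge <- ifelse(st$polarity == "acidic",
                             ifelse(st$protonated, 0L, -1L),
                             ifelse(st$protonated, 1L, 0L))
  st$donor_capable <- ifelse(st$polarity == "acidic",
                             st$protonated,          # COOH / SH / OH donor
                             TRUE)                   # N-H present either way
  st$acceptor_capable <- ifelse(st$polarity == "acidic",
                                TRUE,                # carbonyl/carboxylate O
                                !st$protonated)      # neutral amine/imidazole
  is_his <- st$group == "side_chain" & st$resid == "HIS"
  st$aromatic_ring_neutral <- ifelse(is_his, !st$protonated, NA)
  attr(st, "pH") <- pH
  class(st) <- c("protonation", "data.frame")
  st
}

#' Residues that change protonation state between two pH values
#'
#' A group shifts between `ph_a` and `ph_b` exactly when its pKa lies in the
#' half-open interval `(min(ph_a, ph_b), max(ph_a, ph_b)]` under the tie
#' convention of [assign_states].  Terminal groups are reported but
#' flagged so that downstream patch analysis can exclude them.
#'
#' @param pkas a `pka_set`.
#' @param ph_a,ph_b the two pH values (order-independent).
#' @return A data frame of class `shift_report`: pKa-set keys plus
#'   `charge_low`, `charge_high` (formal charges at the lower/higher pH),
#'   `delta_formal_charge` (`charge_high - charge_low`) and `is_terminal`;
#'   attributes `ph_low`, `ph_high`.
#' @export
shifting_residues <- function(pkas, ph_a, ph_b) {
  if (ph_a == ph_b) stop("the two pH values must differ")
  ph_low <- min(ph_a, ph_b); ph_high <- max(ph_a, ph_b)
  lo <- assign_states(pkas, ph_low)
  hi <- assign_states(pkas, ph_high)
  shift <- lo$formal_charge != hi$formal_charge
  out <- as.data.frame(pkas)[shift, , drop = FALSE]
  out$charge_low <- lo$formal_charge[shift]
  out$charge_high <- hi$formal_charge[shift]
  out$delta_formal_charge <- out$charge_high - out$charge_low
  out$is_terminal <- out$group != "side_chain"
  rownames(out) <- NULL
  attr(out, "ph_low") <- ph_low
  attr(out, "ph_high") <- ph_high
  class(out) <- c("shift_report", "data.frame")
  out
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf("Protonation shift report, pH %.2f vs %.2f: %d shifting group(s)\n",
              attr(x, "ph_low"), attr(x, "ph_high"), nrow(x)))
  if (nrow(x) > 0)
    print.data.frame(x[, c("key", "resid", "group", "pka",
                           "charge_low", "charge_high")])
  invisible(x)
}
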