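#' Fractional side-chain charge of a residue at a given pH
#'
#' Solves the Henderson-Hasselbalch equation for a single amino acid.  An
#' acidic group carries charge \eqn{-1/(1+10^{pKa-pH})}, a basic group
#' \eqn{+1/(1+10^{pH-pKa})}; the thirteen non-ionizable standard residues
#' carry exactly zero.  Vectorized over `aa` (and `pH` by recycling).
#'
#' @param aa character vector of one-letter residue codes.
#' @param pH pH value(s) in (0, 14).
#' @param table a [pka_table].
#' @param nonstandard policy for codes outside the 20 standard residues:
#'   `"zero"` treats `X, B, Z, U, O, J` as non-ionizable with a warning,
#'   `"error"` rejects them.  Unknown characters are always rejected.
#' @return numeric vector of fractional charges in \[-1, 1\].
#' @examples
#' residue_partial_charge("D", 3.8)   # -0.5 at the midpoint
#' residue_partial_charge("K", 8.5)   # +0.990...
#' @export
residue_partial_charge <- function(aa, pH, table = default_pka_table(),
                                   nonstandard = c("zero", "error")) {
  nonstandard <- match.arg(nonstandard)
  if (any(pH <= 0 | pH > 14)) stop("pH must lie in (0, 14]")
  aa <- toupper(aa)
  bad <- !(aa %in% c(STANDARD_AA, NONSTANDARD_AA))
  if (any(bad))
    stop("unknown residue code(s): ", paste(unique(aa[bad]), collapse = ", "))
  ns <- aa %in% NONSTANDARD_AA
  if (any(ns)) {
    if (nonstandard == "error")
      stop("non-standard residue code(s): ",
           paste(unique(aa[ns]), collapse = ", "))
    warning("treating non-standard residue code(s) ",
            paste(unique(aa[ns]), collapse = ", "), " as non-ionizable")
  }
  charge <- numeric(length(aa))
  pH <- rep_len(pH, length(aa))
  ion <- aa %in% names(table$side_chain)
  if (any(ion)) {
    pka <- table$side_chain[aa[ion]]
    acidic <- table$polarity[aa[ion]] == "acidic"
    q <- ifelse(acidic,
                -1 / (1 + 10^(pka - pH[ion])),
                +1 / (1 + 10^(pH[ion] - pka)))
    charge[ion] <- q
  }
  unname(charge)
}

# charge contributions of the free termini
terminal_charge <- function(pH, table, which = c("n", "c")) {
  which <- match.arg(which)
  if (which == "n") 1 / (1 + 10^(pH - table$n_terminus))
  else              -1 / (1 + 10^(table$c_terminus - pH))
}

#' Per-residue charge profile of a sequence at two pH values
#'
#' Computes the fractional charge of every residue at a reference pH and a pH
#' of interest, their difference, and the overall charge score: the sum of
#' charges at the pH of interest minus the sum at the reference pH, divided
#' by the number of residues.
#'
#' @param seq amino-acid string (whitespace and gap characters are stripped);
#'   or a character vector of single letters.
#' @param ph_ref reference pH.
#' @param ph_int pH of interest.
#' @param table a [pka_table].
#' @param include_termini if `TRUE` (default) the first and last residues
#'   additionally carry the N- and C-terminal group charges.
#' @param sequence_id identifier stored with the profile.
#' @inheritParams residue_partial_charge
#' @return A data frame of class `charge_profile` with columns `position`,
#'   `aa`, `charge_ref`, `charge_int`, `delta`, and attributes
#'   `sequence_id`, `include_termini`, `ph_ref`, `ph_int` and `score`
#'   (retrievable with [overall_charge_score]).
#' @examples
#' p <- sequence_charge_profile("DKHG", ph_ref = 7, ph_int = 4)
#' overall_charge_score(p)
#' @export
sequence_charge_profile <- function(seq, ph_ref, ph_int,
                                    table = default_pka_table(),
                                    include_termini = TRUE,
                                    sequence_id = "seq",
                                    nonstandard = c("zero", "error")) {
  nonstandard <- match.arg(nonstandard)
  if (length(seq) == 1L) seq <- strsplit(seq, "")[[1]]
  seq <- toupper(seq[!seq %in% c(" ", "\t", "\n", "\r", "-", ".", "*")])
  if (length(seq) == 0L) stop("empty sequence")
  for (p in c(ph_ref, ph_int))
    if (p <= 0 || p > 14) stop("pH must lie in (0, 14]")
  n <- length(seq)
  charge_ref <- residue_partial_charge(seq, ph_ref, table, nonstandard)
  # suppress the duplicate non-standard-code warning on the second evaluation
  charge_int <- suppressWarnings(
    residue_partial_charge(seq, ph_int, table, nonstandard))
  if (include_termini) {
    charge_ref[1] <- charge_ref[1] + terminal_charge(ph_ref, table, "n")
    charge_int[1] <- charge_int[1] + terminal_charge(ph_int, table, "n")
    charge_ref[n] <- charge_ref[n] + terminal_charge(ph_ref, table, "c")
    charge_int[n] <- charge_int[n] + terminal_charge(ph_int, table, "c")
  }
  out <- data.frame(position = seq_len(n), aa = seq,
                    charge_ref = charge_ref, charge_int = charge_int,
                    delta = charge_int - charge_ref,
                    stringsAsFactors = FALSE)
  attr(out, "sequence_id") <- sequence_id
  attr(out, "include_termini") <- include_termini
  attr(out, "ph_ref") <- ph_ref
  attr(out, "ph_int") <- ph_int
  attr(out, "score") <- (sum(charge_int) - sum(charge_ref)) / n
  class(out) <- c("charge_profile", "data.frame")
  out
}

#' Overall charge score of a profile
#'
#' The per-protein pH-sensitivity statistic: the sum of residue charges at
#' the pH of interest minus the sum at the reference pH, normalized by the
#' number of residues.  Raising the pH can only deprotonate groups, so the
#' score is non-positive whenever `ph_int > ph_ref`.
#'
#' @param profile a `charge_profile` from [sequence_charge_profile].
#' @return a single dimensionless number.
#' @export
overall_charge_score <- function(profile) {
  if (!inherits(profile, "charge_profile"))
    stop("profile must be a charge_profile")
  if (nrow(profile) < 1L) stop("profile has no residues")
  (sum(profile$charge_int) - sum(profile$charge_ref)) / nrow(profile)
}

#' @export
print.charge_profile <- function(x, ...) {
  cat(sprintf("Charge profile of '%s' (%d residues), pH %.2f -> %.2f%s\n",
              attr(x, "sequence_id"), nrow(x), attr(x, "ph_ref"),
              attr(x, "ph_int"),
              if (attr(x, "include_termini")) ", termini included" else ""))
  cat(sprintf("Overall charge score: %+.6f\n", attr(x, "score")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more residues\n")
  invisible(x)
}

#' Rank sequences by pH responsiveness over a pH scan
#'
#' For every consecutive pair of a pH grid (reference = lower value,
#' interest = higher value) computes the overall charge score of each
#' sequence, then ranks sequences by the absolute value of the mean of their
#' per-shift scores.  Ties are broken deterministically by sequence id.
#'
#' @param records named character vector of sequences (names are ids), or a
#'   data frame with columns `id` and `sequence`.
#' @param grid strictly increasing pH values with at least two points;
#'   default `1:14`, i.e. one-unit shifts from pH 1 to 14.
#' @param max_records soft cap on the number of records (default 10000);
#'   exceeding it is an error unless `force = TRUE`.
#' @param force allow more than `max_records` records.
#' @inheritParams sequence_charge_profile
#' @return A list of class `ph_scan_rank` with components `ranking` (data
#'   frame: `id`, `mean_score`, `rank`), `scores` (matrix of per-shift
#'   scores, one row per sequence, one column per grid step) and `skipped`
#'   (ids of records that failed validation).
#' @export
ph_scan_rank <- function(records, grid = 1:14, table = default_pka_table(),
                         include_termini = TRUE, max_records = 10000,
                         force = FALSE, nonstandard = c("zero", "error")) {
  nonstandard <- match.arg(nonstandard)
  if (is.data.frame(records)) {
    stopifnot(all(c("id", "sequence") %in% names(records)))
    ids <- as.character(records$id); seqs <- as.character(records$sequence)
  } else {
    ids <- names(records); seqs <- as.character(records)
  }
  if (is.null(ids) || any(!nzchar(ids))) stop("every record needs an id")
  if (anyDuplicated(ids)) stop("duplicate sequence ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(ids) < 1L) stop("no records")
  if (length(ids) > max_records && !force)
    stop("more than ", max_records, " records; use force = TRUE to override")
  if (length(grid) < 2L || any(diff(grid) <= 0))
    stop("grid must be strictly increasing with at least two points")

  n_shift <- length(grid) - 1L
  scores <- matrix(NA_real_, length(ids), n_shift,
                   dimnames = list(ids, paste0(grid[-length(grid)], "->", grid[-1])))
  skipped <- character(0)
  for (i in seq_along(ids)) {
    prof <- tryCatch(
      suppressWarnings(sequence_charge_profile(
        seqs[i], grid[1], grid[2], table, include_termini,
        sequence_id = ids[i], nonstandard = nonstandard)),
      error = function(e) e)
    if (inherits(prof, "error")) {
      warning("skipping record '", ids[i], "': ", conditionMessage(prof))
      skipped <- c(skipped, ids[i])
      next
    }
    # per-residue charges at every grid point; score of a shift is the
    # normalized difference of consecutive column sums
    aa <- prof$aa
    n <- length(aa)
    colsum <- vapply(grid, function(p) {
      q <- suppressWarnings(residue_partial_charge(aa, p, table, nonstandard))
      if (include_termini)
        q[1] <- q[1] + terminal_charge(p, table, "n")
      if (include_termini)
        q[n] <- q[n] + terminal_charge(p, table, "c")
      sum(q)
    }, numeric(1))
    scores[i, ] <- diff(colsum) / n
  }
  keep <- !(ids %in% skipped)
  if (!any(keep)) stop("no valid records after skipping")
  mean_score <- rowMeans(scores[keep, , drop = FALSE])
  ord <- order(-abs(mean_score), ids[keep])
  ranking <- data.frame(id = ids[keep][ord],
                        mean_score = unname(mean_score[ord]),
                        rank = seq_along(ord),
                        stringsAsFactors = FALSE)
  out <- list(ranking = ranking, scores = scores[keep, , drop = FALSE],
              skipped = skipped, grid = grid)
  class(out) <- "ph_scan_rank"
  out
}

#' @export
print.ph_scan_rank <- function(x, ...) {
  cat(sprintf("pH scan over grid [%s]: %d sequences ranked, %d skipped\n",
              paste(range(x$grid), collapse = ", "),
              nrow(x$ranking), length(x$skipped)))
  print.data.frame(utils::head(x$ranking, 10))
  invisible(x)
}
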