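# ionizable one-letter codes and group polarity used throughout structure mode
IONIZABLE_AA1 <- c("D", "E", "C", "Y", "H", "K", "R")
GROUP_POLARITY <- c(D = "acidic", E = "acidic", C = "acidic", Y = "acidic",
                    H = "basic", K = "basic", R = "basic",
                    n_term = "basic", c_term = "acidic")

new_pka_set <- function(df, version = NULL) {
  rownames(df) <- NULL
  attr(df, "version") <- version
  class(df) <- c("pka_set", "data.frame")
  df
}

#' Assign model pKa values to a structure
#'
#' The environment-free baseline pKa provider: every ionizable side chain
#' (Asp, Glu, Cys, Tyr, His, Lys, Arg) receives the intrinsic pKa from a
#' [pka_table], and the first and last standard residue of each chain
#' receive the terminal-group pKa values.
#'
#' @param model a `structure_model`.
#' @param table a [pka_table].
#' @return A `pka_set`: data frame with columns `chain`, `resno`, `insert`,
#'   `resid`, `group` (`side_chain`, `n_term` or `c_term`), `pka`, `source`,
#'   `key`.
#' @export
assign_model_pkas <- function(model, table = default_pka_table()) {
  rt <- residue_table(model)
  rt <- rt[rt$is_standard, , drop = FALSE]
  if (nrow(rt) == 0L) stop("model has no standard residues")
  side <- rt[rt$aa %in% IONIZABLE_AA1, , drop = FALSE]
  rows <- list()
  if (nrow(side) > 0L)
    rows$side <- data.frame(chain = side$chain, resno = side$resno,
                            insert = side$insert, resid = side$resid,
                            group = "side_chain",
                            pka = unname(table$side_chain[side$aa]),
                            stringsAsFactors = FALSE)
  for (ch in unique(rt$chain)) {
    sub <- rt[rt$chain == ch, , drop = FALSE]
    first <- sub[1, ]; last <- sub[nrow(sub), ]
    rows[[paste0("t", ch)]] <- data.frame(
      chain = c(first$chain, last$chain),
      resno = c(first$resno, last$resno),
      insert = c(first$insert, last$insert),
      resid = c(first$resid, last$resid),
      group = c("n_term", "c_term"),
      pka = c(table$n_terminus, table$c_terminus),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df$source <- "model_table"
  df$key <- res_key(df$chain, df$resno, df$insert)
  new_pka_set(df)
}

#' Parse PROPKA output into a pKa set
#'
#' Reads the `SUMMARY OF THIS PREDICTION` block of a PROPKA `.pka` output
#' file and matches each line to a residue of the bound structure model.
#' Lines referring to residues absent from the (possibly trimmed) model are
#' skipped with a warning, as are duplicate entries (first occurrence kept)
#' and disulfide-bonded cysteines reported with the pKa 99.99 convention.
#' `N+`/`C-` lines are mapped to the terminal groups.
#'
#' @param pka path to a `.pka` file, or its text content.
#' @param model the `structure_model` the predictions refer to.
#' @return a `pka_set` with source `"predictor_file"`; the predictor version
#'   (when present in the file) is stored in the `version` attribute.
#' @export
parse_propka <- function(pka, model) {
  if (length(pka) == 1L && !grepl("\n", pka) && file.exists(pka)) {
    lines <- readLines(pka, warn = FALSE)
  } else {
    lines <- unlist(strsplit(pka, "\n", fixed = TRUE), use.names = FALSE)
  }
  version <- NULL
  vline <- grep("propka", lines, ignore.case = TRUE, value = TRUE)
  if (length(vline) > 0) {
    vm <- regmatches(vline[1], regexpr("[0-9]+\\.[0-9][0-9.]*", vline[1]))
    if (length(vm) > 0) version <- vm
  }
  i_sum <- grep("SUMMARY OF THIS PREDICTION", lines)
  if (length(i_sum) == 0L) stop("no SUMMARY OF THIS PREDICTION block found")
  block <- lines[seq(i_sum[1] + 1L, length(lines))]
  stop_at <- which(grepl("^-{5,}", block) |
                     grepl("Free energy", block, ignore.case = TRUE))
  if (length(stop_at) > 0) block <- block[seq_len(stop_at[1] - 1L)]

  # summary lines: "   ASP  38 A     3.85       3.80" (icode, if any,
  # appended to the residue number)
  pat <- "^\\s*(N\\+|C-|[A-Z]{3})\\s+(-?\\d+)([A-Za-z]?)\\s+(\\S)\\s+(-?\\d+\\.\\d+)"
  m <- regmatches(block, regexec(pat, block))
  parsed <- Filter(function(x) length(x) == 6, m)
  if (length(parsed) == 0L) stop("SUMMARY block contains no parsable pKa lines")

  rt <- residue_table(model)
  rows <- list(); seen <- character(0)
  for (p in parsed) {
    grp3 <- p[2]; resno <- as.integer(p[3]); icode <- p[4]; chain <- p[5]
    pka_val <- as.numeric(p[6])
    group <- switch(grp3, "N+" = "n_term", "C-" = "c_term", "side_chain")
    hit <- rt$chain == chain & rt$resno == resno & rt$insert == icode
    if (!any(hit)) {
      warning("skipping pKa line for ", grp3, " ", resno, " ", chain,
              ": residue not in model")
      next
    }
    if (sum(hit) > 1)
      stop("ambiguous residue match for ", grp3, " ", resno, " ", chain)
    resid <- rt$resid[hit]
    if (group == "side_chain" && grp3 != resid) {
      warning("skipping pKa line for ", grp3, " ", resno, " ", chain,
              ": model residue is ", resid)
      next
    }
    id <- paste(chain, resno, icode, group)
    if (id %in% seen) {
      warning("duplicate pKa entry for ", grp3, " ", resno, " ", chain,
              "; keeping first occurrence")
      next
    }
    if (pka_val > 90) {
      warning(grp3, " ", resno, " ", chain,
              " reported with pKa ", pka_val,
              " (coupled/disulfide convention); treated as non-ionizable")
      next
    }
    seen <- c(seen, id)
    rows[[id]] <- data.frame(chain = chain, resno = resno, insert = icode,
                             resid = resid, group = group, pka = pka_val,
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no pKa entries matched the model")
  df <- do.call(rbind, rows)
  df$source <- "predictor_file"
  df$key <- res_key(df$chain, df$resno, df$insert)
  new_pka_set(df, version = version)
}

#' Run the PROPKA predictor on a structure model
#'
#' Writes the model as PDB, invokes the PROPKA executable (`propka3` or
#' `propka` on the search path) and parses the resulting `.pka` file with
#' [parse_propka].
#'
#' @param model a `structure_model`.
#' @param workdir writable working directory for predictor input/output.
#' @param exe optional explicit path to the predictor executable.
#' @return a `pka_set` with source `"predictor_run"`.
#' @export
run_propka <- function(model, workdir = tempdir(), exe = NULL) {
  if (is.null(exe)) {
    for (cand in c("propka3", "propka")) {
      if (nzchar(Sys.which(cand))) { exe <- cand; break }
    }
  }
  if (is.null(exe) || !nzchar(Sys.which(exe)))
    stop("PROPKA executable not found on PATH; supply archived predictor ",
         "output via parse_propka()/--pka-file instead")
  if (!dir.exists(workdir) || file.access(workdir, 2) != 0)
    stop("workdir '", workdir, "' is not a writable directory")
  pdb_path <- file.path(workdir, paste0(model$structure_id, ".pdb"))
  write_structure(model, pdb_path)
  status <- system2(exe, shQuote(pdb_path), stdout = TRUE, stderr = TRUE)
  pka_path <- file.path(workdir, paste0(model$structure_id, ".pka"))
  if (!is.null(attr(status, "status")) || !file.exists(pka_path))
    stop("PROPKA run failed:\n", paste(status, collapse = "\n"))
  out <- parse_propka(pka_path, model)
  out$source <- "predictor_run"
  out
}

#' @export
print.pka_set <- function(x, ...) {
  v <- attr(x, "version")
  cat(sprintf("pKa set: %d entries (%d side chains, %d termini), source %s%s\n",
              nrow(x), sum(x$group == "side_chain"),
              sum(x$group != "side_chain"),
              paste(unique(x$source), collapse = "/"),
              if (!is.null(v)) paste0(", predictor version ", v) else ""))
  invisible(x)
}
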