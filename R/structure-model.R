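# 3-letter -> 1-letter mapping for the 20 standard residues
AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# common chemically-modified residues and their parent standard residue
COMMON_SUBSTITUTIONS <- c(MSE = "M", SEC = "C", PYL = "K", HYP = "P",
                          SEP = "S", TPO = "T", PTR = "Y", CSO = "C")

WATER_RESID <- c("HOH", "WAT", "DOD", "H2O")
NUCLEIC_RESID <- c("DA", "DC", "DG", "DT", "DU", "DI",
                   "A", "C", "G", "U", "I", "T", "N")

# canonical residue key "chain:resno[insert]"
res_key <- function(chain, resno, insert = "") {
  ins <- ifelse(is.na(insert) | insert == "", "", insert)
  ch <- ifelse(is.na(chain) | chain == "", "_", chain)
  paste0(ch, ":", resno, ins)
}

#' Parse a PDB-format structure into a structure model
#'
#' Reads ATOM records of the first MODEL block into an internal atom table.
#' HETATM records, waters and nucleic acids are excluded; alternate locations
#' are resolved to the highest-occupancy conformer (ties prefer the blank or
#' 'A' indicator).  Parsing of the fixed-column format is delegated to
#' \pkg{bio3d}.
#'
#' @param pdb path to a PDB file, or PDB-format text (a single string with
#'   newlines or a character vector of lines).
#' @param chains optional character vector of chain identifiers to keep.
#' @param provenance `"experimental"`, `"predicted-model"` (B-factor column
#'   holds pLDDT), or `"auto"` (default: predicted-model if the header
#'   mentions AlphaFold, else experimental).
#' @param structure_id identifier stored with the model.
#' @return An object of class `structure_model`: a list with `structure_id`,
#'   `atoms` (data frame with chain, resno, insert, resid, elety, element,
#'   x, y, z, o, b), and `provenance`.
#' @export
parse_structure <- function(pdb, chains = NULL,
                            provenance = c("auto", "experimental",
                                           "predicted-model"),
                            structure_id = "structure") {
  provenance <- match.arg(provenance)
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
    if (identical(structure_id, "structure"))
      structure_id <- sub("\\.(pdb|ent)$", "", basename(pdb))
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
  }

  if (provenance == "auto") {
    provenance <- if (any(grepl("ALPHAFOLD", toupper(utils::head(lines, 50)))))
      "predicted-model" else "experimental"
  }

  # restrict to the first MODEL block of multi-model (e.g. NMR) files
  i_model <- grep("^MODEL", lines)
  if (length(i_model) > 0) {
    i_end <- grep("^ENDMDL", lines)
    stop_at <- if (length(i_end) > 0) i_end[1] else length(lines) + 1L
    keep <- c(seq_len(i_model[1] - 1L),
              seq(i_model[1] + 1L, stop_at - 1L))
    lines <- lines[keep]
  }

  # validate coordinate records before handing off to the reader
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  for (i in which(is_atom)) {
    ln <- lines[i]
    ok <- nchar(ln) >= 54 &&
      !anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                           substr(ln, 39, 46),
                                           substr(ln, 47, 54)))))
    if (!ok) stop("malformed ATOM record at line ", i, ": ", ln)
  }
  if (!any(is_atom)) stop("no ATOM records found")

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdbobj <- suppressWarnings(bio3d::read.pdb(tmp, rm.alt = FALSE,
                                             verbose = FALSE))
  at <- pdbobj$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c(WATER_RESID, NUCLEIC_RESID)), , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no standard amino-acid residues after filtering",
         if (!is.null(chains)) paste0(" (chains ",
                                      paste(chains, collapse = ","), ")"))

  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  at$chain <- ifelse(is.na(at$chain), "", at$chain)
  at$alt <- ifelse(is.na(at$alt), "", at$alt)
  at$o <- ifelse(is.na(at$o), 1.0, at$o)
  at$b <- ifelse(is.na(at$b), 0.0, at$b)

  # resolve alternate locations: highest occupancy, tie -> blank then 'A'
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  if (anyDuplicated(akey)) {
    ord <- order(akey, -at$o, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                               sep = "\r")), , drop = FALSE]
    # restore file order
    at <- at[order(at$eleno), , drop = FALSE]
  }

  atoms <- data.frame(
    eleno = at$eleno, elety = at$elety, resid = at$resid,
    chain = at$chain, resno = at$resno, insert = at$insert,
    x = at$x, y = at$y, z = at$z, o = at$o, b = at$b,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(gsub("[0-9]", "", at$elety), 1, 1), at$elesy),
    stringsAsFactors = FALSE
  )
  if (!any(atoms$resid %in% names(AA3TO1)))
    stop("no standard amino-acid residues after filtering")

  model <- list(structure_id = structure_id, atoms = atoms,
                provenance = provenance)
  class(model) <- "structure_model"
  model
}

#' Residue-level view of a structure model
#'
#' @param model a `structure_model`.
#' @return data frame with one row per residue in file order: `chain`,
#'   `resno`, `insert`, `resid`, `aa` (one-letter, `X` for nonstandard),
#'   `is_standard`, `n_atoms`, `mean_b` (mean B-factor, i.e. pLDDT for
#'   predicted models) and `key`.
#' @export
residue_table <- function(model) {
  at <- model$atoms
  key <- res_key(at$chain, at$resno, at$insert)
  idx <- !duplicated(key)
  df <- data.frame(chain = at$chain[idx], resno = at$resno[idx],
                   insert = at$insert[idx], resid = at$resid[idx],
                   stringsAsFactors = FALSE)
  df$aa <- unname(AA3TO1[df$resid])
  df$is_standard <- !is.na(df$aa)
  df$aa[!df$is_standard] <- "X"
  df$n_atoms <- as.vector(table(key)[key[idx]])
  df$mean_b <- as.vector(tapply(at$b, key, mean)[key[idx]])
  df$key <- key[idx]
  rownames(df) <- NULL
  df
}

#' @export
print.structure_model <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("Structure model '%s' (%s): %d atoms, %d residues, chains %s\n",
              x$structure_id, x$provenance, nrow(x$atoms), nrow(rt),
              paste(unique(rt$chain), collapse = ",")))
  invisible(x)
}

# accept keep_ranges as list of c(chain, start, end) or "A:10-50" strings
parse_keep_ranges <- function(keep_ranges) {
  if (is.null(keep_ranges)) return(NULL)
  if (is.data.frame(keep_ranges)) return(keep_ranges)
  rows <- lapply(keep_ranges, function(k) {
    if (is.character(k) && length(k) == 1L) {
      m <- regmatches(k, regexec("^(\\w+):(-?\\d+)-(-?\\d+)$", k))[[1]]
      if (length(m) != 4) stop("cannot parse keep range '", k,
                               "'; expected CHAIN:START-END")
      data.frame(chain = m[2], start = as.integer(m[3]),
                 end = as.integer(m[4]), stringsAsFactors = FALSE)
    } else {
      data.frame(chain = as.character(k[1]), start = as.integer(k[2]),
                 end = as.integer(k[3]), stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Trim low-confidence regions from a predicted model
#'
#' Removes residues whose mean pLDDT (stored in the B-factor column, the
#' AlphaFold convention) is below `threshold`, except residues covered by an
#' explicit keep range (e.g. an inter-domain linker that should be retained
#' despite low confidence).
#'
#' @param model a `structure_model` with provenance `"predicted-model"`.
#' @param threshold pLDDT cutoff; residues with mean pLDDT below it are
#'   dropped.  Default 70, the usual low-confidence boundary.
#' @param keep_ranges ranges exempt from trimming: a data frame with columns
#'   `chain`, `start`, `end`, or a list of `"CHAIN:START-END"` strings.
#' @return the trimmed `structure_model`; attribute `removed` lists the keys
#'   of removed residues.
#' @export
trim_by_confidence <- function(model, threshold = 70, keep_ranges = NULL) {
  if (model$provenance != "predicted-model")
    stop("confidence trimming applies only to predicted models ",
         "(pLDDT in the B-factor column)")
  kr <- parse_keep_ranges(keep_ranges)
  rt <- residue_table(model)
  low <- rt$mean_b < threshold
  if (!is.null(kr)) {
    for (i in seq_len(nrow(kr))) {
      inr <- rt$chain == kr$chain[i] & rt$resno >= kr$start[i] &
        rt$resno <= kr$end[i]
      low <- low & !inr
    }
  }
  removed <- rt$key[low]
  at <- model$atoms
  keep <- !(res_key(at$chain, at$resno, at$insert) %in% removed)
  if (!any(keep)) stop("confidence trimming removed every residue")
  model$atoms <- at[keep, , drop = FALSE]
  attr(model, "removed") <- removed
  model
}

#' Extract per-chain amino-acid sequences from a structure model
#'
#' @param model a `structure_model`.
#' @param common_substitutions if `TRUE`, map common modified residues to
#'   their parent standard residue (e.g. selenomethionine MSE to M) instead
#'   of `X`.
#' @return named character vector, one sequence string per chain.
#' @export
extract_sequence <- function(model, common_substitutions = FALSE) {
  rt <- residue_table(model)
  map <- AA3TO1
  if (common_substitutions) map <- c(map, COMMON_SUBSTITUTIONS)
  aa <- map[rt$resid]
  aa[is.na(aa)] <- "X"
  vapply(split(aa, factor(rt$chain, levels = unique(rt$chain))),
         paste, character(1), collapse = "")
}

# fixed-column PDB ATOM line formatting (wwPDB v3.30 columns)
format_pdb_atom <- function(eleno, elety, resid, chain, resno, insert,
                            x, y, z, o, b, element) {
  name <- ifelse(nchar(elety) >= 4, substr(elety, 1, 4),
                 sprintf(" %-3s", elety))
  sprintf("ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          eleno %% 100000L, name, resid, substr(paste0(chain, " "), 1, 1),
          resno, substr(paste0(insert, " "), 1, 1), x, y, z, o, b, element)
}

#' Write a structure model as PDB-format text
#'
#' @param model a `structure_model`.
#' @param path optional output file; if `NULL` the lines are returned.
#' @return character vector of PDB lines (invisibly when `path` is given).
#' @export
write_structure <- function(model, path = NULL) {
  at <- model$atoms
  lines <- format_pdb_atom(seq_len(nrow(at)), at$elety, at$resid, at$chain,
                           at$resno, at$insert, at$x, at$y, at$z, at$o,
                           at$b, at$element)
  # TER after the last residue of each chain
  out <- character(0)
  for (ch in unique(at$chain)) {
    out <- c(out, lines[at$chain == ch], "TER")
  }
  out <- c(out, "END")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}
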