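# On-disk formats: the 3-line annotated FASTA dialect used for training
# data, plain FASTA input, prediction TSV and GFF3 region output.
#
# Annotated record:
#   >id|ORGANISM_GROUP|CLASS
#   MKK...           amino acid sequence
#   SSS...OOO        per-residue annotation over {S,T,L,P,I,M,O}

#' Read the 3-line annotated FASTA dialect
#'
#' @param path File path.
#' @return List of [annotated_sp()] records (CS recovered as the last
#'   SP-tagged annotation position).
#' @export
read_annotated_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 3L != 0L)
    stop("malformed annotated FASTA: number of non-empty lines (",
         length(lines), ") is not a multiple of 3")
  recs <- list()
  for (k in seq_len(length(lines) / 3L)) {
    lh <- lines[3L * k - 2L]; ls <- lines[3L * k - 1L]; la <- lines[3L * k]
    lineno <- 3L * k - 2L
    if (!startsWith(lh, ">"))
      stop("line ", lineno, ": expected a '>' header, got: ", substr(lh, 1, 30))
    fields <- strsplit(sub("^>", "", lh), "|", fixed = TRUE)[[1]]
    if (length(fields) != 3L)
      stop("line ", lineno, ": header must be >id|GROUP|CLASS")
    id <- fields[1]; group <- fields[2]; cls <- fields[3]
    if (!cls %in% SP_CLASSES)
      stop("line ", lineno, " (record ", id, "): unknown class ", cls)
    if (!group %in% ORGANISM_GROUPS_EXT)
      stop("line ", lineno, " (record ", id, "): unknown group ", group)
    if (nchar(ls) != nchar(la))
      stop("line ", lineno, " (record ", id,
           "): sequence and annotation lengths differ (",
           nchar(ls), " vs ", nchar(la), ")")
    ach <- split_chars(la)
    if (!all(ach %in% c("S", "T", "L", "P", "I", "M", "O")))
      stop("line ", lineno, " (record ", id, "): bad annotation characters")
    sp_char <- unname(SP_ANNOT_CHAR[cls])
    cs <- NA_integer_
    if (is_sp_class(cls)) {
      sp_pos <- which(ach == sp_char)
      if (!length(sp_pos) || any(ach[seq_len(max(sp_pos))] != sp_char))
        stop("line ", lineno, " (record ", id,
             "): annotation inconsistent with class ", cls)
      cs <- max(sp_pos)
    } else if (any(ach %in% c("S", "T", "L", "P"))) {
      stop("line ", lineno, " (record ", id,
           "): SP annotation characters in a NO_SP record")
    }
    recs[[k]] <- annotated_sp(ls, cls, cs = cs, organism_group = group,
                              id = id, annotation = la)
  }
  recs
}

#' Write records in the 3-line annotated FASTA dialect
#'
#' @param records List of [annotated_sp()] records; records lacking an
#'   `annotation` get one synthesized from class and CS.
#' @param path Output path.
#' @return `path`, invisibly. Write-then-read round-trips.
#' @export
write_annotated_fasta <- function(records, path) {
  lines <- unlist(lapply(records, function(r) {
    ann <- r$annotation
    if (is.null(ann)) {
      T <- nchar(r$sequence)
      ann <- if (is_sp_class(r$sp_class))
        paste0(strrep(unname(SP_ANNOT_CHAR[r$sp_class]), r$cs),
               strrep("O", T - r$cs))
      else strrep("I", T)
    }
    c(paste0(">", r$id, "|", r$organism_group, "|", r$sp_class),
      r$sequence, ann)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read plain FASTA into named sequences
#'
#' @param path FASTA file.
#' @return Named character vector of amino acid sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  s <- as.character(x)
  names(s) <- sub("\\s.*$", "", names(x))
  s
}

#' Write a prediction table as TSV
#'
#' Columns: id, predicted_class, the six class probabilities, cs ("-" when
#' none), cs_prob.
#'
#' @param pred data.frame from [predict_records()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(pred, path) {
  out <- pred
  out$cs <- ifelse(is.na(out$cs), "-", as.character(out$cs))
  out$cs_prob <- ifelse(is.na(out$cs_prob), "-",
                        formatC(out$cs_prob, digits = 6, format = "f"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write region calls as GFF3 on protein coordinates
#'
#' One feature per contiguous region run (1-based, inclusive), feature type
#' `sig_peptide_region`, attributes carrying the region tag.
#'
#' @param region_tables Named list (by sequence id) of data.frames from
#'   [summarize_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_gff3 <- function(region_tables, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (id in names(region_tables)) {
    tab <- region_tables[[id]]
    if (is.null(tab) || !nrow(tab)) next
    writeLines(sprintf(
      "%s\tsigcrf\tsig_peptide_region\t%d\t%d\t.\t.\t.\tID=%s.%s;region=%s",
      id, tab$start, tab$end, id, tab$region, tab$region), con)
  }
  invisible(path)
}
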