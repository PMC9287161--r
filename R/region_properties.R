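# Physicochemical summaries of predicted or annotated regions: length,
# mean Kyte-Doolittle hydrophobicity and net charge at pH 7. Used to check
# that region calls match the literature (positively charged n-region,
# hydrophobic h-region, polar c-region).

#' Mean Kyte-Doolittle hydrophobicity of a region
#'
#' @param region_seq Amino acid string; non-standard residues are excluded
#'   from the mean.
#' @return Arithmetic mean of per-residue hydropathy values.
#' @export
hydrophobicity <- function(region_seq) {
  if (!nzchar(region_seq)) stop("empty region")
  v <- KD_SCALE[split_chars(toupper(region_seq))]
  v <- v[!is.na(v)]
  if (!length(v)) stop("region has no standard residues")
  mean(v)
}

#' Net charge of a region at pH 7
#'
#' Sums residue charges (K, R = +1; D, E = -1; H = `his_charge`, default
#' 0). In Eukarya and Archaea the initiator methionine is not formylated,
#' so an N-terminal region gains one extra positive charge from its free
#' amino group; in bacteria the formylated start contributes none.
#'
#' @param region_seq Amino acid string.
#' @param organism_group One of [ORGANISM_GROUPS] (or `"UNKNOWN"`, treated
#'   as formylated/no extra charge).
#' @param is_n_terminal Does the region start at residue 1?
#' @param his_charge Charge assigned to histidine (default 0).
#' @return Net charge in elementary charges.
#' @export
net_charge <- function(region_seq, organism_group = "UNKNOWN",
                       is_n_terminal = FALSE, his_charge = 0) {
  if (!nzchar(region_seq)) stop("empty region")
  check_group(organism_group)
  ch <- split_chars(toupper(region_seq))
  q <- CHARGE_PH7[ch]
  q[ch == "H"] <- his_charge
  q[is.na(q)] <- 0
  extra <- if (is_n_terminal && organism_group %in% c("EUKARYA", "ARCHAEA")) 1 else 0
  sum(q) + extra
}

#' Summarize the regions of a decoded prediction
#'
#' Contiguous runs of each region tag along the Viterbi path become one
#' summary row each (SP-region tags only; the mature part is not
#' summarized). The run containing residue 1 receives the N-terminal
#' amino-group charge rule.
#'
#' @param prediction An `sp_prediction` (or any list with `path`).
#' @param sequence The amino acid sequence that was predicted.
#' @param organism_group Organism group for the charge rule.
#' @param space State space (defaults to the canonical one).
#' @return data.frame with columns region, start, end, length,
#'   hydrophobicity, net_charge; zero rows when the path has no SP states.
#' @export
summarize_regions <- function(prediction, sequence, organism_group = "UNKNOWN",
                              space = build_state_space()) {
  path <- prediction$path
  tags <- space$states$tag[path]
  is_sp <- space$states$is_sp_state[path]
  empty <- data.frame(region = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      hydrophobicity = numeric(0), net_charge = numeric(0),
                      stringsAsFactors = FALSE)
  if (!any(is_sp)) return(empty)
  r <- rle(tags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- is_sp[starts]
  rows <- lapply(which(keep), function(k) {
    seg <- substr(sequence, starts[k], ends[k])
    data.frame(region = r$values[k], start = starts[k], end = ends[k],
               length = r$lengths[k],
               hydrophobicity = hydrophobicity(seg),
               net_charge = net_charge(seg, organism_group,
                                       is_n_terminal = starts[k] == 1L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Region summaries from a known label path
#'
#' Convenience wrapper: builds the true state path of an annotated SP from
#' its region labels (taking the first admissible state at ambiguous
#' positions is not meaningful, so this uses the singleton backbone of the
#' generator annotation instead) and summarizes it.
#'
#' @param tags Character vector of region tags per position (e.g. the
#'   generator's `region_tags`).
#' @param sequence Amino acid sequence.
#' @param organism_group Organism group for the charge rule.
#' @return As [summarize_regions()].
#' @export
summarize_tag_runs <- function(tags, sequence, organism_group = "UNKNOWN") {
  sp_tags <- c("N", "N1", "N2", "H", "C", "R1", "R2", "L1", "L2", "L3", "P")
  r <- rle(tags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% sp_tags
  rows <- lapply(which(keep), function(k) {
    seg <- substr(sequence, starts[k], ends[k])
    data.frame(region = r$values[k], start = starts[k], end = ends[k],
               length = r$lengths[k],
               hydrophobicity = hydrophobicity(seg),
               net_charge = net_charge(seg, organism_group,
                                       is_n_terminal = starts[k] == 1L),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) return(summarize_regions(list(path = integer(0)), sequence))
  do.call(rbind, rows)
}
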