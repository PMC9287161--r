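# Rule-based generation of multitag (weak supervision) region labels for
# annotated signal peptides.
#
# The rules: the initial n-region has a minimum length of two residues and
# the terminal c-region a minimum of three; the most hydrophobic position
# (7-residue Kyte-Doolittle window) belongs to the h-region; everything
# between these six fixed positions is ambiguous ({n,h} or {h,c}). Tat SPs
# place the n-h border at the twin-arginine motif (two dedicated states,
# then one more n position); SPII SPs have no c-region - the last three SP
# positions are the lipobox and positions between the h-center and the
# lipobox are h only; SPIII SPs get a single undifferentiated SP state.

#' Construct an annotated signal peptide record
#'
#' @param sequence Amino acid sequence (full protein, not just the SP).
#' @param sp_class One of [SP_CLASSES].
#' @param cs 1-based position of the last SP residue (cleavage falls between
#'   `cs` and `cs + 1`); `NA` for `NO_SP`.
#' @param organism_group One of [ORGANISM_GROUPS].
#' @param id Optional record identifier used in error messages.
#' @param annotation Optional per-residue annotation string (3-line format).
#' @return An object of class `annotated_sp`.
#' @export
annotated_sp <- function(sequence, sp_class, cs = NA_integer_,
                         organism_group = "UNKNOWN", id = "seq",
                         annotation = NULL) {
  check_class(sp_class)
  check_group(organism_group)
  T <- nchar(sequence)
  if (is_sp_class(sp_class)) {
    if (is.na(cs) || cs < 1L || cs >= T)
      stop("record ", id, ": SP class ", sp_class,
           " requires 1 <= cs < sequence length")
  } else {
    cs <- NA_integer_
  }
  structure(list(id = id, sequence = toupper(sequence), sp_class = sp_class,
                 cs = as.integer(cs), organism_group = organism_group,
                 annotation = annotation),
            class = "annotated_sp")
}

# Kyte-Doolittle values for a sequence; unknown residues get 0 (neutral).
kd_values <- function(seq_chars) {
  v <- KD_SCALE[seq_chars]
  v[is.na(v)] <- 0
  unname(v)
}

#' Locate the h-region center of a signal peptide
#'
#' Slides a 7-residue window over the SP, sums Kyte-Doolittle hydropathies,
#' and returns the center of the maximum-sum window, leftmost on ties.
#' Admissible centers keep a 2-residue n-region and 3-residue c-region
#' satisfiable. For SPs of length 6 (window does not fit) the single residue
#' with maximal hydropathy within the admissible range is used.
#'
#' @param sp_seq The SP part of the sequence (positions 1..cs).
#' @param lo Optional lower bound on the returned center (used for Tat SPs,
#'   where the h-region must start after the post-motif n position).
#' @return 1-based center position.
#' @export
find_h_center <- function(sp_seq, lo = 3L) {
  L <- nchar(sp_seq)
  if (L < 6L) stop("SP too short for h-center search (length ", L, " < 6)")
  kd <- kd_values(split_chars(sp_seq))
  hi <- L - 3L
  if (lo > hi) stop("no admissible h-center in [", lo, ", ", hi, "]")
  clo <- max(lo, 4L)
  if (L >= 7L && clo <= hi) {
    centers <- clo:hi
    sums <- vapply(centers, function(i) sum(kd[(i - 3L):(i + 3L)]), 0)
    return(centers[which.max(sums)])
  }
  # window does not fit (L == 6, or Tat motif leaves no full-window center):
  # fall back to the single most hydrophobic admissible residue
  cand <- seq.int(lo, hi)
  cand[which.max(kd[cand])]
}

#' Locate the twin-arginine motif
#'
#' Returns the leftmost position `m >= 3` such that residues `m` and `m + 1`
#' are both arginine, keeping the minimum 2-residue n-region before the
#' motif.
#'
#' @param sp_seq The SP part of the sequence.
#' @return 1-based index of the first motif arginine.
#' @export
find_rr_motif <- function(sp_seq) {
  ch <- split_chars(sp_seq)
  L <- length(ch)
  if (L >= 4L) {
    for (m in 3L:(L - 1L)) if (ch[m] == "R" && ch[m + 1L] == "R") return(m)
  }
  stop("no admissible twin-arginine (RR) motif at position >= 3")
}

# Internal: build a multitag matrix (list of integer vectors of state row
# indices) of length T, given per-position tag sets for the SP part.
.mt_new <- function(T) vector("list", T)

#' Generate multitag region labels for an annotated SP
#'
#' Applies the class-specific labeling rules and returns, for every
#' position, the set of admissible CRF states: singletons at the fixed
#' positions (n-region start, h-center, c-region end, motif, lipobox),
#' two-element ambiguous sets ({n,h} before the h-center, {h,c} after it)
#' elsewhere inside the SP, and the class's own `O` mature state after the
#' cleavage site.
#'
#' @param sp An [annotated_sp()] with an SP class.
#' @param space A state space from [build_state_space()].
#' @return An object of class `multitag_matrix`: a list of length `T` of
#'   integer vectors of state row indices (1-based into `space$states`).
#' @export
label_regions <- function(sp, space) {
  if (!is_sp_class(sp$sp_class))
    stop("record ", sp$id, ": label_regions requires an SP class")
  cls <- sp$sp_class
  cs <- sp$cs
  T <- nchar(sp$sequence)
  sp_seq <- substr(sp$sequence, 1L, cs)
  mt <- .mt_new(T)
  S <- function(...) vapply(list(...), function(tg) state_idx(space, cls, tg), 0L)
  fail <- function(msg) stop("record ", sp$id, " (", cls, ", cs=", cs, "): ", msg)

  if (cls == "SEC_SPIII") {
    for (t in seq_len(cs)) mt[[t]] <- S("P")
  } else if (cls %in% c("SEC_SPI", "SEC_SPII")) {
    if (cs < 6L) fail("SP shorter than 6 residues, rules unsatisfiable")
    i <- find_h_center(sp_seq)
    mt[[1L]] <- S("N"); mt[[2L]] <- S("N")
    if (i > 3L) for (t in 3L:(i - 1L)) mt[[t]] <- S("N", "H")
    if (cls == "SEC_SPI") {
      mt[[i]] <- S("H")
      if (i + 1L <= cs - 3L) for (t in (i + 1L):(cs - 3L)) mt[[t]] <- S("H", "C")
      for (t in (cs - 2L):cs) mt[[t]] <- S("C")
    } else {
      for (t in i:(cs - 3L)) mt[[t]] <- S("H")
      mt[[cs - 2L]] <- S("L1"); mt[[cs - 1L]] <- S("L2"); mt[[cs]] <- S("L3")
    }
  } else { # TAT_SPI / TAT_SPII
    if (cs < 6L) fail("SP shorter than 6 residues, rules unsatisfiable")
    m <- tryCatch(find_rr_motif(sp_seq), error = function(e) fail(conditionMessage(e)))
    tail_min <- if (cls == "TAT_SPI") 4L else 3L # h + min c / lipobox
    if (m + 2L > cs - tail_min) fail("RR motif too close to the cleavage site")
    i <- find_h_center(sp_seq, lo = m + 3L)
    if (i > cs - 3L) fail("h-center collides with the c-region/lipobox")
    for (t in seq_len(m - 1L)) mt[[t]] <- S("N1")
    mt[[m]] <- S("R1"); mt[[m + 1L]] <- S("R2"); mt[[m + 2L]] <- S("N2")
    if (i > m + 3L) for (t in (m + 3L):(i - 1L)) mt[[t]] <- S("N2", "H")
    if (cls == "TAT_SPI") {
      mt[[i]] <- S("H")
      if (i + 1L <= cs - 3L) for (t in (i + 1L):(cs - 3L)) mt[[t]] <- S("H", "C")
      for (t in (cs - 2L):cs) mt[[t]] <- S("C")
    } else {
      for (t in i:(cs - 3L)) mt[[t]] <- S("H")
      mt[[cs - 2L]] <- S("L1"); mt[[cs - 1L]] <- S("L2"); mt[[cs]] <- S("L3")
    }
  }
  if (cs < T) for (t in (cs + 1L):T) mt[[t]] <- state_idx(space, cls, "O")
  structure(mt, class = "multitag_matrix")
}

# Multitag labels for any record, including NO_SP (mature annotation chars
# I/M/O map to the NO_SP class's own states; missing annotation means "I").
record_multitag <- function(rec, space) {
  if (is_sp_class(rec$sp_class)) return(label_regions(rec, space))
  T <- nchar(rec$sequence)
  ann <- rec$annotation
  ch <- if (is.null(ann)) rep("I", T) else split_chars(ann)
  if (length(ch) != T)
    stop("record ", rec$id, ": annotation length != sequence length")
  if (!all(ch %in% c("I", "M", "O")))
    stop("record ", rec$id, ": NO_SP annotation must use I/M/O only")
  mt <- lapply(ch, function(x) state_idx(space, "NO_SP", x))
  structure(mt, class = "multitag_matrix")
}

#' Serialize a multitag matrix as per-position tag-set strings
#'
#' @param mt A `multitag_matrix`.
#' @param space The state space it refers to.
#' @return Character vector, one element per position, e.g. `"N+H"`.
#' @export
format_multitag <- function(mt, space) {
  vapply(mt, function(ix) paste(space$states$tag[ix], collapse = "+"), "")
}
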