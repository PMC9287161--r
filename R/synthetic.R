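# Synthetic sequence generator.
#
# Emulates the compositional structure of the five SP types plus soluble
# and transmembrane negatives: a positively charged n-region, a
# leucine-rich hydrophobic h-region, a small-polar c-region ending in an
# A-x-A-like motif, a twin-arginine RR dimer at the n-h border of Tat SPs,
# a lipobox triplet (followed by the lipidated cysteine) for SPII types,
# and an undifferentiated short SP for SPIII. Composition tables are free
# inventions tuned so a small encoder can learn the classes; they are
# configuration, not claims about real SP statistics.

.comp <- function(...) { w <- c(...); w / sum(w) }

GEN_COMP <- list(
  # n-region, Sec (K/R rich)
  n_sec = .comp(K = 0.30, R = 0.12, A = 0.10, S = 0.10, T = 0.08, N = 0.08,
                Q = 0.07, L = 0.05, I = 0.05, G = 0.05),
  # n-region, Tat (K only among basics so the RR dimer is unambiguous)
  n_tat = .comp(K = 0.38, A = 0.12, S = 0.12, T = 0.09, N = 0.09, Q = 0.08,
                L = 0.06, G = 0.06),
  h = .comp(L = 0.35, A = 0.14, V = 0.15, I = 0.14, F = 0.10, M = 0.05,
            W = 0.04, G = 0.03),
  c = .comp(S = 0.24, T = 0.18, A = 0.22, G = 0.14, N = 0.11, Q = 0.11),
  # SPIII (prepilin): short, polar/basic, no substructure
  p = .comp(K = 0.15, Q = 0.15, S = 0.15, T = 0.12, A = 0.12, G = 0.10,
            E = 0.08, L = 0.07, I = 0.06),
  mature = .comp(A = 0.08, R = 0.05, N = 0.05, D = 0.06, C = 0.02, Q = 0.05,
                 E = 0.07, G = 0.07, H = 0.02, I = 0.05, L = 0.09, K = 0.06,
                 M = 0.02, F = 0.04, P = 0.05, S = 0.07, T = 0.06, W = 0.01,
                 Y = 0.03, V = 0.05),
  soluble = .comp(A = 0.07, R = 0.06, N = 0.06, D = 0.07, C = 0.01, Q = 0.06,
                  E = 0.09, G = 0.08, H = 0.03, I = 0.03, L = 0.06, K = 0.08,
                  M = 0.02, F = 0.02, P = 0.06, S = 0.09, T = 0.07, W = 0.01,
                  Y = 0.03, V = 0.03)
)

#' Generator configuration
#'
#' @param counts Named integer vector of per-class record counts.
#' @param n_len,h_len,c_len Inclusive length ranges of the n-, h- and
#'   c-regions.
#' @param sp3_len Length range of the undifferentiated SPIII SP.
#' @param mature_len Length range of the mature part.
#' @param tm_len Length range of the transmembrane segment of TM negatives.
#' @param tm_fraction Fraction of `NO_SP` records that are transmembrane.
#' @param group_probs Per-group sampling proportions (restricted per class
#'   to biologically sensible groups).
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return A `generator_config` list.
#' @export
generator_config <- function(counts = c(NO_SP = 170, SEC_SPI = 150,
                                        SEC_SPII = 100, SEC_SPIII = 50,
                                        TAT_SPI = 80, TAT_SPII = 50),
                             n_len = c(2L, 10L), h_len = c(7L, 15L),
                             c_len = c(3L, 7L), sp3_len = c(8L, 20L),
                             mature_len = c(20L, 45L), tm_len = c(15L, 22L),
                             tm_fraction = 0.4,
                             group_probs = c(ARCHAEA = 0.15, EUKARYA = 0.3,
                                             GRAM_POS = 0.25, GRAM_NEG = 0.3),
                             seed = 1L) {
  stopifnot(all(counts >= 0), all(names(counts) %in% SP_CLASSES),
            n_len[2] >= n_len[1], n_len[1] >= 2L)
  structure(as.list(environment()), class = "generator_config")
}

.rseq <- function(n, comp) paste(sample(names(comp), n, replace = TRUE,
                                        prob = comp), collapse = "")
.rlen <- function(rng) sample(seq.int(rng[1], rng[2]), 1L)

# Groups a class may be sampled from (eukaryotes lack Tat/SPII, SPII, SPIII).
.class_groups <- list(
  NO_SP = ORGANISM_GROUPS,
  SEC_SPI = ORGANISM_GROUPS,
  SEC_SPII = c("GRAM_POS", "GRAM_NEG"),
  SEC_SPIII = c("ARCHAEA", "GRAM_POS", "GRAM_NEG"),
  TAT_SPI = c("ARCHAEA", "GRAM_POS", "GRAM_NEG"),
  TAT_SPII = c("GRAM_POS", "GRAM_NEG")
)

# One synthetic record; returns annotated_sp with region tag metadata.
.gen_record <- function(cls, group, cfg, id) {
  ann_char <- SP_ANNOT_CHAR[cls]
  if (cls == "NO_SP") {
    tm <- stats::runif(1) < cfg$tm_fraction
    if (tm) {
      nin <- .rlen(c(10L, 25L)); ntm <- .rlen(cfg$tm_len); nout <- .rlen(c(10L, 25L))
      seq <- paste0("M", .rseq(nin - 1L, GEN_COMP$soluble),
                    .rseq(ntm, GEN_COMP$h), .rseq(nout, GEN_COMP$soluble))
      ann <- paste0(strrep("I", nin), strrep("M", ntm), strrep("O", nout))
      tags <- c(rep("I", nin), rep("M", ntm), rep("O", nout))
    } else {
      L <- .rlen(c(30L, 70L))
      seq <- paste0("M", .rseq(L - 1L, GEN_COMP$soluble))
      ann <- strrep("I", L)
      tags <- rep("I", L)
    }
    rec <- annotated_sp(seq, "NO_SP", organism_group = group, id = id,
                        annotation = ann)
    rec$region_tags <- tags
    return(rec)
  }

  if (cls == "SEC_SPIII") {
    spl <- .rlen(cfg$sp3_len)
    sp_seq <- paste0("M", .rseq(spl - 1L, GEN_COMP$p))
    tags <- rep("P", spl)
  } else if (cls %in% c("SEC_SPI", "SEC_SPII")) {
    nl <- .rlen(cfg$n_len); hl <- .rlen(cfg$h_len)
    nreg <- paste0("M", .rseq(nl - 1L, GEN_COMP$n_sec))
    hreg <- .rseq(hl, GEN_COMP$h)
    if (cls == "SEC_SPI") {
      cl <- .rlen(cfg$c_len)
      creg <- split_chars(.rseq(cl, GEN_COMP$c))
      creg[cl - 2L] <- "A"; creg[cl] <- "A"   # A-x-A motif before the CS
      sp_seq <- paste0(nreg, hreg, paste(creg, collapse = ""))
      tags <- c(rep("N", nl), rep("H", hl), rep("C", cl))
    } else {
      lipo <- paste0("L", sample(c("A", "S", "T", "V"), 1L),
                     sample(c("G", "A"), 1L))
      sp_seq <- paste0(nreg, hreg, lipo)
      tags <- c(rep("N", nl), rep("H", hl), "L1", "L2", "L3")
    }
  } else { # Tat classes
    n1 <- .rlen(c(2L, 5L)); n2 <- .rlen(c(1L, 3L)); hl <- .rlen(cfg$h_len)
    n1reg <- paste0("M", .rseq(n1 - 1L, GEN_COMP$n_tat))
    n2reg <- .rseq(n2, GEN_COMP$n_tat)
    hreg <- .rseq(hl, GEN_COMP$h)
    if (cls == "TAT_SPI") {
      cl <- .rlen(cfg$c_len)
      creg <- split_chars(.rseq(cl, GEN_COMP$c))
      creg[cl - 2L] <- "A"; creg[cl] <- "A"
      sp_seq <- paste0(n1reg, "RR", n2reg, hreg, paste(creg, collapse = ""))
      tags <- c(rep("N1", n1), "R1", "R2", rep("N2", n2), rep("H", hl),
                rep("C", cl))
    } else {
      lipo <- paste0("L", sample(c("A", "S", "T", "V"), 1L),
                     sample(c("G", "A"), 1L))
      sp_seq <- paste0(n1reg, "RR", n2reg, hreg, lipo)
      tags <- c(rep("N1", n1), "R1", "R2", rep("N2", n2), rep("H", hl),
                "L1", "L2", "L3")
    }
  }
  cs <- nchar(sp_seq)
  ml <- .rlen(cfg$mature_len)
  mature <- .rseq(ml, GEN_COMP$mature)
  if (cls %in% c("SEC_SPII", "TAT_SPII"))
    mature <- paste0("C", substr(mature, 2L, ml))  # lipidated cysteine
  seq <- paste0(sp_seq, mature)
  ann <- paste0(strrep(ann_char, cs), strrep("O", ml))
  rec <- annotated_sp(seq, cls, cs = cs, organism_group = group, id = id,
                      annotation = ann)
  rec$region_tags <- c(tags, rep("O", ml))
  rec
}

#' Generate a labeled synthetic dataset
#'
#' @param config A [generator_config()].
#' @return List of [annotated_sp()] records, each additionally carrying
#'   `region_tags` (the generator's true region tag per position). Class
#'   counts match the config exactly; organism groups are sampled from the
#'   config proportions restricted to each class's plausible groups.
#' @export
generate_dataset <- function(config = generator_config()) {
  set.seed(config$seed)
  recs <- list()
  k <- 0L
  for (cls in names(config$counts)) {
    gset <- .class_groups[[cls]]
    gp <- config$group_probs[gset] / sum(config$group_probs[gset])
    for (i in seq_len(config$counts[[cls]])) {
      k <- k + 1L
      group <- sample(gset, 1L, prob = gp)
      recs[[k]] <- .gen_record(cls, group, config,
                               id = sprintf("%s_%04d", tolower(cls), i))
    }
  }
  recs
}

#' Generate sequence families with known homology structure
#'
#' Fixture for the partitioning module: families of point-mutated copies of
#' random seed sequences. Within-family identity is about `1 -
#' mutation_rate`; between-family identity is that of unrelated random
#' sequences, well below typical partition thresholds.
#'
#' @param n_families Number of families.
#' @param members Members per family.
#' @param seq_len Length of the seed sequences.
#' @param mutation_rate Per-residue substitution probability in `(0, 1)`.
#' @param seed RNG seed.
#' @return List of records (class `NO_SP`, groups cycling) carrying a
#'   `family` field.
#' @export
generate_homology_families <- function(n_families = 6L, members = 5L,
                                       seq_len = 60L, mutation_rate = 0.05,
                                       seed = 1L) {
  stopifnot(mutation_rate > 0, mutation_rate < 1)
  set.seed(seed)
  recs <- list()
  k <- 0L
  for (f in seq_len(n_families)) {
    seed_seq <- split_chars(.rseq(seq_len, GEN_COMP$mature))
    for (m in seq_len(members)) {
      ch <- seed_seq
      mut <- which(stats::runif(seq_len) < mutation_rate)
      if (length(mut))
        ch[mut] <- sample(AA20, length(mut), replace = TRUE)
      k <- k + 1L
      rec <- annotated_sp(paste(ch, collapse = ""), "NO_SP",
                          organism_group = ORGANISM_GROUPS[(f - 1L) %% 4L + 1L],
                          id = sprintf("fam%02d_m%02d", f, m),
                          annotation = strrep("I", seq_len))
      rec$family <- f
      recs[[k]] <- rec
    }
  }
  recs
}
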