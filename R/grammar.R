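# Region grammar: CRF state space, class <-> state mapping and the
# allowed-transition mask that enforces region order.
#
# Each SP class owns private copies of the mature states (O, M, I) so that
# every CRF state maps to exactly one global class; summing marginals over a
# class's states therefore yields a proper distribution over classes.

# Region tag sequences of the SP part of each class. Mature tags O/M/I are
# appended for every class; NO_SP has only mature states.
.SP_TAGS <- list(
  NO_SP     = character(0),
  SEC_SPI   = c("N", "H", "C"),
  SEC_SPII  = c("N", "H", "L1", "L2", "L3"),
  SEC_SPIII = "P",
  TAT_SPI   = c("N1", "R1", "R2", "N2", "H", "C"),
  TAT_SPII  = c("N1", "R1", "R2", "N2", "H", "L1", "L2", "L3")
)

# Tags that may repeat (self-transition). Motif tags R1/R2 and the lipobox
# L1/L2/L3 are fixed-length: no self-transitions, single outgoing edge.
.REPEATABLE <- c("N", "N1", "N2", "H", "C", "P", "I", "M", "O")

#' Build the canonical CRF state space
#'
#' Constructs the full grammar over all six sequence classes: the per-class
#' region states (n/h/c regions, twin-arginine motif `R1 R2`, lipobox
#' `L1 L2 L3`, undifferentiated `P` for Sec/SPIII) plus per-class copies of
#' the mature-protein states `O` (outside/secreted), `M` (membrane) and `I`
#' (inside/cytosol), and the transition mask that forces regions to appear
#' in their biological order.
#'
#' Within an SP class the only allowed moves are along the region order
#' (with self-loops on variable-length regions); the last SP state exits
#' into the class's own `O` state. `NO_SP` sequences may start in `I`, `M`
#' or `O`; SP classes must start in their first SP state. Any state may end
#' a sequence, so sequences of every length are decodable.
#'
#' @return An object of class `sp_state_space`: a list with `states` (a
#'   data.frame with columns `id` (0-based, dense), `class`, `tag`,
#'   `is_sp_state`), the `C x C` logical matrix `allowed`, and logical
#'   vectors `start_allowed`, `end_allowed`.
#' @examples
#' space <- build_state_space()
#' nrow(space$states)
#' @export
build_state_space <- function() {
  states <- do.call(rbind, lapply(SP_CLASSES, function(cls) {
    tags <- c(.SP_TAGS[[cls]], c("O", "M", "I"))
    data.frame(class = cls, tag = tags,
               is_sp_state = !(tags %in% c("O", "M", "I")),
               stringsAsFactors = FALSE)
  }))
  states$id <- seq_len(nrow(states)) - 1L
  states <- states[, c("id", "class", "tag", "is_sp_state")]
  C <- nrow(states)
  allowed <- matrix(FALSE, C, C)
  lab <- paste(states$class, states$tag, sep = ".")
  rownames(allowed) <- colnames(allowed) <- lab
  idx <- function(cls, tag) which(states$class == cls & states$tag == tag)

  for (cls in SP_CLASSES) {
    sp_tags <- .SP_TAGS[[cls]]
    # chain along the SP region order, self-loops on repeatable tags
    if (length(sp_tags)) {
      for (k in seq_along(sp_tags)) {
        if (sp_tags[k] %in% .REPEATABLE)
          allowed[idx(cls, sp_tags[k]), idx(cls, sp_tags[k])] <- TRUE
        nxt <- if (k < length(sp_tags)) sp_tags[k + 1] else "O"
        allowed[idx(cls, sp_tags[k]), idx(cls, nxt)] <- TRUE
      }
    }
    # mature topology, shared by every class
    o <- idx(cls, "O"); m <- idx(cls, "M"); i <- idx(cls, "I")
    allowed[o, o] <- TRUE; allowed[o, m] <- TRUE
    allowed[m, m] <- TRUE; allowed[m, i] <- TRUE; allowed[m, o] <- TRUE
    allowed[i, i] <- TRUE; allowed[i, m] <- TRUE
  }

  start_allowed <- rep(FALSE, C)
  for (cls in SP_CLASSES) {
    first <- if (length(.SP_TAGS[[cls]])) .SP_TAGS[[cls]][1] else c("I", "M", "O")
    for (tg in first) start_allowed[idx(cls, tg)] <- TRUE
  }
  end_allowed <- rep(TRUE, C)

  structure(list(states = states, allowed = allowed,
                 start_allowed = start_allowed, end_allowed = end_allowed),
            class = "sp_state_space")
}

#' States belonging to one sequence class
#'
#' @param space A state space from [build_state_space()].
#' @param g A class name from [SP_CLASSES].
#' @return The subset of `space$states` with `class == g`.
#' @export
states_of_class <- function(space, g) {
  check_class(g)
  space$states[space$states$class == g, , drop = FALSE]
}

# Row indices (1-based) of the states of class g.
class_state_idx <- function(space, g) which(space$states$class == g)

# Row indices of SP states (any class).
sp_state_idx <- function(space) which(space$states$is_sp_state)

# Row index of a single (class, tag) state.
state_idx <- function(space, cls, tag) {
  which(space$states$class == cls & space$states$tag == tag)
}

#' Export the transition mask as a plain-text adjacency table
#'
#' Writes one row per allowed transition: `from_class from_tag to_class
#' to_tag`, tab-separated, plus start/end admissibility columns in a header
#' block of state rows. Intended for manual inspection of the grammar.
#'
#' @param space A state space.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_adjacency <- function(space, path) {
  st <- space$states
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# states: id\tclass\ttag\tis_sp_state\tstart\tend", con)
  writeLines(sprintf("state\t%d\t%s\t%s\t%d\t%d\t%d", st$id, st$class, st$tag,
                     as.integer(st$is_sp_state),
                     as.integer(space$start_allowed),
                     as.integer(space$end_allowed)), con)
  writeLines("# transitions: from_id\tto_id\tfrom\tto", con)
  ij <- which(space$allowed, arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  writeLines(sprintf("edge\t%d\t%d\t%s.%s\t%s.%s",
                     st$id[ij[, 1]], st$id[ij[, 2]],
                     st$class[ij[, 1]], st$tag[ij[, 1]],
                     st$class[ij[, 2]], st$tag[ij[, 2]]), con)
  invisible(path)
}
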