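# What an agent can see.
#
# Every agent always sees its own cell and the 8 Moore-adjacent cells, plus
# any cell within Euclidean distance r (between integer cell centers) whose
# skill label matches the agent's own. Collaboration extends the skill match
# to the labels of the agent's network neighbors; copying instead adds the
# cells those neighbors currently occupy. Boundaries clip; there is no
# wraparound.

#' Perception parameters
#'
#' @param r Perception radius in cell units; Euclidean distance between cell
#'   centers, inclusive (`<= r`). Default 6. `r = 2 * sqrt(2)` reaches all
#'   offsets up to `(+/-2, +/-2)`.
#' @return An object of class `perception_params`.
#' @export
perception_params <- function(r = 6) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0) {
    stop_param("`r` must be a single number >= 0")
  }
  structure(list(r = as.numeric(r)), class = "perception_params")
}

#' Construct an agent
#'
#' @param id Agent index.
#' @param skill Skill label in `1..s`.
#' @param row,col Current position (1-based cell indices).
#' @return An object of class `agent`.
#' @export
agent <- function(id, skill, row, col) {
  structure(
    list(id = as.integer(id), skill = as.integer(skill),
         row = as.integer(row), col = as.integer(col)),
    class = "agent"
  )
}

# Offset table for radius r: every (dr, dc) != (0, 0) that is Moore-adjacent
# or within the perception disk, with per-offset flags. Cached per r.
.offset_cache <- new.env(parent = emptyenv())

disk_offsets <- function(r) {
  key <- format(r, digits = 17)
  hit <- .offset_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- max(1L, as.integer(floor(r)))
  dr <- rep(-m:m, times = 2L * m + 1L)
  dc <- rep(-m:m, each = 2L * m + 1L)
  in_disk <- dr * dr + dc * dc <= r * r
  moore <- pmax(abs(dr), abs(dc)) == 1L
  keep <- (in_disk | moore) & !(dr == 0L & dc == 0L)
  off <- list(dr = dr[keep], dc = dc[keep],
              in_disk = in_disk[keep], moore = moore[keep])
  .offset_cache[[key]] <- off
  off
}

# Core enumerator: linear (column-major) indices of the cells visible from
# (row, col) to an agent whose admissible skill set is given as a logical
# lookup over 1..s. Always includes the current cell.
visible_indices <- function(row, col, skill_ok, skill_mat, h, w, r) {
  off <- disk_offsets(r)
  rows <- row + off$dr
  cols <- col + off$dc
  ok <- rows >= 1L & rows <= h & cols >= 1L & cols <= w
  rows <- rows[ok]; cols <- cols[ok]
  idx <- (cols - 1L) * h + rows
  keep <- off$moore[ok] | (off$in_disk[ok] & skill_ok[skill_mat[idx]])
  c((col - 1L) * h + row, idx[keep])
}

skill_lookup <- function(s, labels) {
  ok <- logical(s)
  ok[labels] <- TRUE
  ok
}

idx_to_positions <- function(idx, h) {
  idx <- sort(unique(idx))
  cbind(row = ((idx - 1L) %% h) + 1L, col = ((idx - 1L) %/% h) + 1L)
}

check_agent_in_bounds <- function(a, instance) {
  stopifnot(inherits(a, "agent"), inherits(instance, "problem_instance"))
  if (a$row < 1L || a$row > instance$height || a$col < 1L || a$col > instance$width) {
    stop_param("agent position out of grid bounds")
  }
  if (a$skill < 1L || a$skill > instance$s) {
    stop_param("agent skill label outside 1..s")
  }
}

#' Cells visible to an agent searching on its own
#'
#' The union of the agent's current cell, the up-to-8 Moore-adjacent cells,
#' and every cell whose center lies within Euclidean distance `r` and whose
#' skill label equals the agent's.
#'
#' @param a An [agent()].
#' @param instance A [problem_instance()].
#' @param params A [perception_params()].
#' @return An integer matrix with columns `row`, `col`, one visible cell per
#'   row, sorted; always contains the agent's current cell.
#' @export
individual_visible_set <- function(a, instance, params = perception_params()) {
  check_agent_in_bounds(a, instance)
  ok <- skill_lookup(instance$s, a$skill)
  idx <- visible_indices(a$row, a$col, ok, instance$skills$skill,
                         instance$height, instance$width, params$r)
  idx_to_positions(idx, instance$height)
}

#' Cells visible when collaborating with network neighbors
#'
#' Collaboration widens the skill match: in addition to its individual
#' visible set, the agent sees every cell within distance `r` whose skill
#' matches any neighbor's skill — as though each neighbor answered "given my
#' skills, from where you stand, here is what I would see". Always a
#' superset of [individual_visible_set()].
#'
#' @param a An [agent()].
#' @param neighbor_skills Integer vector of the network neighbors' skill
#'   labels (may be empty).
#' @inheritParams individual_visible_set
#' @return Integer position matrix as in [individual_visible_set()].
#' @export
collaborative_visible_set <- function(a, neighbor_skills, instance,
                                      params = perception_params()) {
  check_agent_in_bounds(a, instance)
  neighbor_skills <- as.integer(neighbor_skills)
  if (length(neighbor_skills) &&
      (any(neighbor_skills < 1L) || any(neighbor_skills > instance$s))) {
    stop_param("neighbor skill labels outside 1..s")
  }
  ok <- skill_lookup(instance$s, c(a$skill, neighbor_skills))
  idx <- visible_indices(a$row, a$col, ok, instance$skills$skill,
                         instance$height, instance$width, params$r)
  idx_to_positions(idx, instance$height)
}

#' Candidate cells considered when copying
#'
#' The individual visible set plus the cells the agent's network neighbors
#' currently occupy (wherever those are on the grid).
#'
#' @param a An [agent()].
#' @param neighbor_positions Integer matrix with columns `row`, `col` (one
#'   neighbor per row), or NULL/empty for no neighbors.
#' @inheritParams individual_visible_set
#' @return Integer position matrix as in [individual_visible_set()].
#' @export
copy_candidate_set <- function(a, neighbor_positions, instance,
                               params = perception_params()) {
  check_agent_in_bounds(a, instance)
  ok <- skill_lookup(instance$s, a$skill)
  idx <- visible_indices(a$row, a$col, ok, instance$skills$skill,
                         instance$height, instance$width, params$r)
  if (!is.null(neighbor_positions) && NROW(neighbor_positions) > 0L) {
    np <- matrix(as.integer(neighbor_positions), ncol = 2L)
    if (any(np[, 1L] < 1L) || any(np[, 1L] > instance$height) ||
        any(np[, 2L] < 1L) || any(np[, 2L] > instance$width)) {
      stop_param("neighbor positions out of grid bounds")
    }
    idx <- c(idx, (np[, 2L] - 1L) * instance$height + np[, 1L])
  }
  idx_to_positions(idx, instance$height)
}
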