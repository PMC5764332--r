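#' Arterial tree representation
#'
#' An arterial tree is a tibble with one row per arterial segment and class
#' `arterial_tree`. Segments are axisymmetric elastic cylinders tapering
#' exponentially from a proximal radius `r_in_cm` to a distal radius
#' `r_out_cm` over `length_cm`. The tree is a binary bifurcation tree: every
#' segment has either two children or none; childless (terminal) segments
#' carry a three-element Windkessel outflow parametrized by a terminal
#' resistance `RT` and compliance `CT` (both stored in plain CGS units,
#' g s^-1 cm^-4 and cm^4 s^2 g^-1).
#'
#' @param segments data frame with columns `id`, `name`, `length_cm`,
#'   `r_in_cm`, `r_out_cm`, `parent_id` (NA for the root) and `RT`, `CT`
#'   (NA for internal segments; CGS units).
#' @return A validated `arterial_tree` tibble with a logical `terminal`
#'   column added.
#' @export
arterial_tree <- function(segments) {
  need <- c("id", "name", "length_cm", "r_in_cm", "r_out_cm", "parent_id", "RT", "CT")
  missing_cols <- setdiff(need, names(segments))
  if (length(missing_cols) > 0) {
    abort(paste0("tree table lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "pw_tree_error")
  }
  tree <- as_tibble(segments)[need]
  tree$id <- as.integer(tree$id)
  tree$parent_id <- as.integer(tree$parent_id)
  tree$terminal <- !is.na(tree$RT) | !is.na(tree$CT)
  validate_tree(tree)
  class(tree) <- c("arterial_tree", class(tibble()))
  tree
}

validate_tree <- function(tree) {
  bad_row <- function(i, msg) {
    abort(sprintf("invalid tree row id=%s: %s", tree$id[i], msg),
          class = "pw_tree_error")
  }
  if (anyDuplicated(tree$id)) {
    abort("duplicated segment ids in tree table", class = "pw_tree_error")
  }
  for (i in seq_len(nrow(tree))) {
    if (!is.finite(tree$length_cm[i]) || tree$length_cm[i] <= 0) bad_row(i, "non-positive length")
    if (!is.finite(tree$r_in_cm[i]) || tree$r_in_cm[i] <= 0 ||
        !is.finite(tree$r_out_cm[i]) || tree$r_out_cm[i] <= 0) bad_row(i, "non-positive radius")
    if (tree$r_out_cm[i] > tree$r_in_cm[i] + 1e-12) bad_row(i, "distal radius exceeds proximal radius")
    if (xor(is.na(tree$RT[i]), is.na(tree$CT[i]))) bad_row(i, "RT and CT must be both present or both absent")
    if (!is.na(tree$RT[i]) && (tree$RT[i] <= 0 || tree$CT[i] <= 0)) bad_row(i, "non-positive terminal RT/CT")
  }
  roots <- which(is.na(tree$parent_id))
  if (length(roots) != 1) {
    abort(sprintf("tree must have exactly one root (found %d)", length(roots)),
          class = "pw_tree_error")
  }
  for (i in seq_len(nrow(tree))) {
    p <- tree$parent_id[i]
    if (!is.na(p) && !p %in% tree$id) bad_row(i, sprintf("parent id %s not in table", p))
  }
  kids <- split(tree$id, factor(tree$parent_id, levels = tree$id))
  n_kids <- lengths(kids)
  for (j in seq_along(n_kids)) {
    sid <- tree$id[j]
    is_term <- tree$terminal[j]
    if (is_term && n_kids[j] != 0) {
      abort(sprintf("invalid tree row id=%s: terminal segment (RT/CT set) has children", sid),
            class = "pw_tree_error")
    }
    if (!is_term && n_kids[j] != 2) {
      abort(sprintf(
        "invalid tree row id=%s: internal segment must have exactly 2 children (has %d)",
        sid, n_kids[j]), class = "pw_tree_error")
    }
  }
  # reachability from the root (also guards against cycles)
  root <- tree$id[roots]
  seen <- root
  frontier <- root
  while (length(frontier) > 0) {
    nxt <- tree$id[tree$parent_id %in% frontier & !is.na(tree$parent_id)]
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (length(seen) != nrow(tree)) {
    abort("not all segments reachable from the root", class = "pw_tree_error")
  }
  invisible(tree)
}

#' Read an arterial tree definition from CSV
#'
#' The CSV schema mirrors the packaged 55-segment table: columns
#' `id,name,length_cm,r_in_cm,r_out_cm,parent_id,RT_1e4_cgs,CT_1e-6_cgs`,
#' with an empty `parent_id` marking the root and empty `RT`/`CT` marking
#' internal segments. The column scale factors (1e4 for resistance, 1e-6 for
#' compliance) are multiplied out on load so the returned tree stores plain
#' CGS values.
#'
#' @param path path to a tree CSV; `#`-prefixed lines are treated as comments.
#' @return An [arterial_tree()].
#' @export
read_tree_csv <- function(path) {
  raw <- read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
  need <- c("id", "name", "length_cm", "r_in_cm", "r_out_cm", "parent_id",
            "RT_1e4_cgs", "CT_1e-6_cgs")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("tree CSV lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "pw_tree_error")
  }
  arterial_tree(tibble(
    id = raw$id,
    name = as.character(raw$name),
    length_cm = as.numeric(raw$length_cm),
    r_in_cm = as.numeric(raw$r_in_cm),
    r_out_cm = as.numeric(raw$r_out_cm),
    parent_id = suppressWarnings(as.integer(raw$parent_id)),
    RT = as.numeric(raw$RT_1e4_cgs) * 1e4,
    CT = as.numeric(raw$`CT_1e-6_cgs`) * 1e-6
  ))
}

#' Write an arterial tree to CSV in the external schema
#'
#' Inverse of [read_tree_csv()]: CGS terminal values are divided back into the
#' 1e4 / 1e-6 column scales.
#'
#' @param tree an [arterial_tree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_csv <- function(tree, path) {
  out <- data.frame(
    id = tree$id,
    name = tree$name,
    length_cm = tree$length_cm,
    r_in_cm = tree$r_in_cm,
    r_out_cm = tree$r_out_cm,
    parent_id = tree$parent_id,
    check.names = FALSE
  )
  out$RT_1e4_cgs <- tree$RT / 1e4
  out$`CT_1e-6_cgs` <- tree$CT / 1e-6
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' The packaged 55-artery systemic tree
#'
#' Loads the nominal (175 cm subject) fifty-five-segment arterial tree
#' shipped with the package.
#'
#' @return An [arterial_tree()] with 55 segments.
#' @export
default_tree <- function() {
  read_tree_csv(system.file("extdata", "arterial_tree_55.csv",
                            package = "pulsewave", mustWork = TRUE))
}

#' Scale a nominal tree to a subject
#'
#' The whole geometry scales with the height ratio `S = height_cm / 175`:
#' every length and radius is multiplied by `S`. Terminal Windkessel
#' parameters scale with the size of the truncated distal beds: each terminal
#' resistance is multiplied by `s_r / S^3` and each terminal compliance by
#' `s_c * S^3`, where `s_r` and `s_c` are the subject-specific global scale
#' factors for terminal resistance and compliance.
#'
#' @param tree an [arterial_tree()] at nominal (175 cm) size.
#' @param height_cm subject height in cm (> 0).
#' @param s_r,s_c terminal resistance / compliance scale factors (> 0).
#' @param ref_height_cm height of the nominal-tree subject (175 cm).
#' @return The scaled [arterial_tree()]; topology unchanged.
#' @export
scale_tree <- function(tree, height_cm, s_r = 1, s_c = 1, ref_height_cm = 175) {
  if (!is.finite(height_cm) || height_cm <= 0) {
    abort("height_cm must be positive", class = "pw_tree_error")
  }
  if (s_r <= 0 || s_c <= 0) {
    abort("s_r and s_c must be positive", class = "pw_tree_error")
  }
  s <- height_cm / ref_height_cm
  out <- tree
  out$length_cm <- tree$length_cm * s
  out$r_in_cm <- tree$r_in_cm * s
  out$r_out_cm <- tree$r_out_cm * s
  out$RT <- tree$RT * s_r / s^3
  out$CT <- tree$CT * s_c * s^3
  attr(out, "subject_scaling") <- list(S = s, s_r = s_r, s_c = s_c)
  out
}

#' Local radius of a tapered segment
#'
#' The unstressed radius tapers exponentially along the segment:
#' `r0(x) = r_in * (r_out / r_in)^(x / L)`, so `log r0` interpolates
#' linearly between `log r_in` and `log r_out`.
#'
#' @param tree an [arterial_tree()].
#' @param id segment id.
#' @param x position(s) along the segment in cm, within `[0, L]`.
#' @return Radius (cm) at each `x`.
#' @export
segment_radius <- function(tree, id, x) {
  i <- match(id, tree$id)
  if (is.na(i)) abort(sprintf("no segment with id %s", id), class = "pw_tree_error")
  L <- tree$length_cm[i]
  if (any(x < -1e-12 | x > L + 1e-12)) {
    abort(sprintf("x outside [0, %g] for segment id %s", L, id), class = "pw_tree_error")
  }
  tree$r_in_cm[i] * (tree$r_out_cm[i] / tree$r_in_cm[i])^(pmin(pmax(x / L, 0), 1))
}

#' Elastic wall model
#'
#' The wall stiffness function `f(r0) = (4/3) (k1 exp(k2 r0) + k3)` relates
#' the unstressed radius to the effective elastic modulus entering the tube
#' law: stiffness rises as vessels narrow (`k1 > 0`, `k2 < 0`). The
#' parameters are global (shared by all segments); `k1` and `k3` are the two
#' subject-specific stiffness parameters, `k2` is fixed.
#'
#' @param k1 in units of 1e7 g s^-2 cm^-1 (nominal 2).
#' @param k2 in cm^-1 (fixed -22.53).
#' @param k3 in units of 1e5 g s^-2 cm^-1 (nominal 8.65).
#' @param p0_mmhg reference distending pressure in mmHg (fixed 97): the
#'   pressure at which each vessel sits at its unstressed area.
#' @return An object of class `wall_model`.
#' @export
wall_model <- function(k1 = 2, k2 = -22.53, k3 = 8.65, p0_mmhg = 97) {
  if (k2 >= 0) abort("k2 must be negative", class = "pw_wall_error")
  if (k1 < 0 || k3 <= 0) abort("k1 must be >= 0 and k3 > 0", class = "pw_wall_error")
  structure(list(k1 = k1, k2 = k2, k3 = k3, p0_mmhg = p0_mmhg),
            class = "wall_model")
}

#' @export
print.wall_model <- function(x, ...) {
  cat(sprintf("<wall_model> k1=%g x1e7, k2=%g /cm, k3=%g x1e5, P0=%g mmHg\n",
              x$k1, x$k2, x$k3, x$p0_mmhg))
  invisible(x)
}

#' Wall elastic modulus at a given unstressed radius
#'
#' @param r0 unstressed radius (cm), positive.
#' @param wall a [wall_model()].
#' @return `f(r0)` in g s^-2 cm^-1 (CGS).
#' @export
wall_modulus <- function(r0, wall = wall_model()) {
  if (any(r0 <= 0)) abort("r0 must be positive", class = "pw_wall_error")
  (4 / 3) * (wall$k1 * 1e7 * exp(wall$k2 * r0) + wall$k3 * 1e5)
}

#' Segment unstressed volume
#'
#' Volume of the exponentially tapered segment, `pi * integral r0(x)^2 dx`
#' (closed form).
#'
#' @param tree an [arterial_tree()].
#' @param id segment id(s); default all.
#' @return Volume(s) in cm^3.
#' @export
segment_volume <- function(tree, id = tree$id) {
  i <- match(id, tree$id)
  L <- tree$length_cm[i]; rin <- tree$r_in_cm[i]; rout <- tree$r_out_cm[i]
  k <- 2 * log(rout / rin) / L
  v <- ifelse(abs(k) < 1e-14,
              pi * rin^2 * L,
              pi * rin^2 * (exp(k * L) - 1) / k)
  v
}

# ids of segments on the unique path between two tree positions; positions are
# (segment id, fractional distance from the proximal end).
tree_path <- function(tree, from_id, to_id) {
  anc <- function(id) {
    out <- id
    while (!is.na(tree$parent_id[match(id, tree$id)])) {
      id <- tree$parent_id[match(id, tree$id)]
      out <- c(out, id)
    }
    out
  }
  a <- anc(from_id); b <- anc(to_id)
  common <- intersect(a, b)
  if (length(common) == 0) abort("segments are not connected", class = "pw_tree_error")
  top <- common[1]
  list(up = a[seq_len(match(top, a))], down = rev(b[seq_len(match(top, b))]))
}

#' Along-tree path length between two probe positions
#'
#' @param tree an [arterial_tree()].
#' @param from_id,to_id segment ids.
#' @param from_frac,to_frac fractional position along each segment (0 =
#'   proximal end, 1 = distal end).
#' @return Path length in cm measured along the vessel centrelines.
#' @export
tree_path_length <- function(tree, from_id, to_id, from_frac = 0, to_frac = 0.5) {
  p <- tree_path(tree, from_id, to_id)
  len <- function(id) tree$length_cm[match(id, tree$id)]
  # only the descending case (from_id an ancestor of to_id) and its mirror are
  # meaningful for transit-time measurements; handle the general V-shaped path
  # for completeness.
  if (length(p$up) == 1 && p$up[1] == from_id) {
    # from is the common ancestor: descend
    mid <- setdiff(p$down, c(from_id, to_id))
    (1 - from_frac) * len(from_id) + sum(len(mid)) + to_frac * len(to_id)
  } else if (p$down[length(p$down)] == to_id && p$down[1] == from_id) {
    (1 - from_frac) * len(from_id) + sum(len(setdiff(p$down, c(from_id, to_id)))) +
      to_frac * len(to_id)
  } else {
    top <- p$up[length(p$up)]
    up_mid <- setdiff(p$up, c(from_id, top))
    down_mid <- setdiff(p$down, c(top, to_id))
    from_frac * len(from_id) + sum(len(up_mid)) + len(top) +
      sum(len(down_mid)) + to_frac * len(to_id)
  }
}
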