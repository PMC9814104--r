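# Conical-intersection exit branching tree: a rooted probability tree whose
# leaves are terminal isomers. Evaluating it gives the predicted yield split
# between recovering the starting isomer and forming the photoisomer;
# inverting it against measured quantum yields recovers the split fractions.

#' Leaf node: a terminal isomer
#'
#' @param isomer `"E"` or `"Z"`.
#' @return a `branch_node` leaf.
#' @export
branch_leaf <- function(isomer = c("E", "Z")) {
  isomer <- match.arg(isomer)
  structure(list(type = "leaf", isomer = isomer), class = "branch_node")
}

#' Internal node with probabilistic outgoing edges
#'
#' @param probs numeric edge probabilities in [0, 1], summing to 1 (to 1e-12).
#' @param children list of `branch_node`s, same length as `probs`.
#' @param labels optional character edge labels (e.g. "path1", "path2'").
#' @return a `branch_node`.
#' @export
branch_node <- function(probs, children, labels = NULL) {
  probs <- as.numeric(probs)
  if (length(probs) != length(children) || length(probs) == 0) {
    stop("probs and children must have equal positive length", call. = FALSE)
  }
  if (any(probs < 0) || any(probs > 1)) {
    stop("edge probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    stop("edge probabilities must sum to 1", call. = FALSE)
  }
  if (!all(vapply(children, inherits, logical(1), "branch_node"))) {
    stop("children must be branch_node objects", call. = FALSE)
  }
  if (is.null(labels)) labels <- rep(NA_character_, length(probs))
  structure(list(type = "node", probs = probs, children = children,
                 labels = labels), class = "branch_node")
}

#' Build the ground-state exit tree for a starting isomer
#'
#' Mechanism: after internal conversion through the conical intersection
#' nearest the starting isomer, the system exits on the ground-state surface.
#' For a Z start the exit splits between the Z side (direct recovery, path 1)
#' and the E side (path 2), where the vibrationally hot ground-state species
#' then branches over the E-Z torsional barrier into Z (path 2') or E
#' (path 2''). For an E start the hydrogen out-of-plane motion blocks the
#' E-side exit, so the system leaves only toward Z (path 3) and the hot
#' species branches over the barrier into E (path 3') or Z (path 3'').
#' Both splits default to the statistical 50:50.
#'
#' @param start_isomer `"E"` or `"Z"` starting isomer.
#' @param exit_split probability of the direct exit toward the starting
#'   isomer at the CI (Z start only; default 0.5).
#' @param barrier_split probability that the hot ground-state species falls
#'   back to the *starting* isomer at the E-Z barrier (default 0.5).
#' @return a `branch_node` tree.
#' @export
build_exit_tree <- function(start_isomer = c("E", "Z"),
                            exit_split = 0.5, barrier_split = 0.5) {
  start_isomer <- match.arg(start_isomer)
  if (exit_split < 0 || exit_split > 1 || barrier_split < 0 || barrier_split > 1) {
    stop("splits must lie in [0, 1]", call. = FALSE)
  }
  if (start_isomer == "Z") {
    barrier <- branch_node(c(barrier_split, 1 - barrier_split),
                           list(branch_leaf("Z"), branch_leaf("E")),
                           labels = c("path2'", "path2''"))
    branch_node(c(exit_split, 1 - exit_split),
                list(branch_leaf("Z"), barrier),
                labels = c("path1", "path2"))
  } else {
    barrier <- branch_node(c(barrier_split, 1 - barrier_split),
                           list(branch_leaf("E"), branch_leaf("Z")),
                           labels = c("path3'", "path3''"))
    branch_node(1, list(barrier), labels = "path3")
  }
}

#' Evaluate terminal isomer yields of a branching tree
#'
#' Sums root-to-leaf probability products by terminal isomer label.
#'
#' @param tree a `branch_node`.
#' @return list with `y_E`, `y_Z` (summing to 1).
#' @export
evaluate_tree <- function(tree) {
  acc <- c(E = 0, Z = 0)
  walk <- function(node, p) {
    if (node$type == "leaf") {
      acc[node$isomer] <<- acc[node$isomer] + p
    } else {
      for (i in seq_along(node$probs)) walk(node$children[[i]], p * node$probs[i])
    }
  }
  walk(tree, 1)
  list(y_E = unname(acc[["E"]]), y_Z = unname(acc[["Z"]]))
}

#' Count leaves of a tree
#' @param tree a `branch_node`.
#' @return integer leaf count.
#' @export
count_leaves <- function(tree) {
  if (tree$type == "leaf") return(1L)
  sum(vapply(tree$children, count_leaves, integer(1)))
}

#' Solve the barrier split that reproduces an observed yield
#'
#' For the two-level trees above, the starting-isomer yield is linear in the
#' barrier split q: Z start y_Z = exit + (1 - exit) q; E start y_E = q.
#' Inverts that relation in closed form; infeasible targets (outside the
#' reachable [min, max] yield range) raise an error carrying the
#' unconstrained solution.
#'
#' @param start_isomer `"E"` or `"Z"`.
#' @param observed_start_yield observed yield of the *starting* isomer in
#'   [0, 1] (e.g. 0.77 for a Z start).
#' @param exit_split fixed CI exit split (Z start; default 0.5).
#' @return list with `barrier_split`, the implied `yields`, and `feasible`.
#' @export
fit_splits <- function(start_isomer = c("E", "Z"), observed_start_yield,
                       exit_split = 0.5) {
  start_isomer <- match.arg(start_isomer)
  y <- observed_start_yield
  if (y < 0 || y > 1) stop("observed yield must lie in [0, 1]", call. = FALSE)
  q <- if (start_isomer == "Z") {
    (y - exit_split) / (1 - exit_split)
  } else {
    y
  }
  if (q < -1e-12 || q > 1 + 1e-12) {
    stop(sprintf(
      "target yield %.3f is infeasible for the %s-start topology (unconstrained barrier split %.3f outside [0, 1])",
      y, start_isomer, q), call. = FALSE)
  }
  q <- min(max(q, 0), 1)
  tree <- build_exit_tree(start_isomer, exit_split = exit_split,
                          barrier_split = q)
  list(barrier_split = q, yields = evaluate_tree(tree), feasible = TRUE)
}
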