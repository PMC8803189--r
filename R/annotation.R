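# Biological interpretation of attractors: marker-signature behavior calls,
# validity and viability of bipartite-model attractors, and deletion-mutant
# identification.

cycle_matrix <- function(att, nodes) {
  m <- do.call(rbind, att$cycle)
  colnames(m) <- nodes
  m
}

#' Marker scheme for behavior classification
#'
#' @param behaviors named list; each element a named 0/1 vector of marker
#'   values that must hold stably (in every cycle state) for that behavior.
#' @param atypical label returned when no behavior matches (default
#'   "atypical").
#' @export
marker_scheme <- function(behaviors, atypical = "atypical") {
  stopifnot(is.list(behaviors), length(names(behaviors)) == length(behaviors))
  structure(list(behaviors = behaviors, atypical = atypical),
            class = "marker_scheme")
}

#' Endothelial-cell behavior markers (angiogenesis models)
#'
#' The standard three-signature scheme over four marker nodes: phalanx
#' (AKT = 1, JAGa = 0, NRP1 = 0), stalk (JAGa = 1, NRP1 = 0) and tip
#' (NRP1 = 1, DLL4a = 1, AKT = 0).  Signatures are partial: markers a
#' behavior does not name are unconstrained.
#'
#' @param akt,jaga,dll4a,nrp1 the node names carrying the four markers in
#'   the network under analysis.
#' @export
ec_marker_scheme <- function(akt = "AKT", jaga = "JAGa", dll4a = "DLL4a",
                             nrp1 = "NRP1") {
  marker_scheme(list(
    phalanx = stats::setNames(c(1L, 0L, 0L), c(akt, jaga, nrp1)),
    stalk = stats::setNames(c(1L, 0L), c(jaga, nrp1)),
    tip = stats::setNames(c(1L, 1L, 0L), c(nrp1, dll4a, akt))))
}

#' Classify an attractor's behavior from marker signatures
#'
#' A behavior label is returned only when every marker it names holds its
#' required value in every cycle state (a stable signature).  An oscillating
#' marker or a non-matching stable configuration yields the atypical label.
#' A user scheme whose signatures overlap on a concrete attractor is a
#' configuration error.
#'
#' @param att a `bn_attractor`.
#' @param scheme a [marker_scheme()].
#' @param nodes node names of the network the attractor belongs to.
#' @return a behavior label (character scalar).
#' @export
classify_behavior <- function(att, scheme, nodes) {
  marker_nodes <- unique(unlist(lapply(scheme$behaviors, names)))
  unknown <- setdiff(marker_nodes, nodes)
  if (length(unknown) > 0L)
    stop("marker node(s) not in the network: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  m <- cycle_matrix(att, nodes)
  matches <- vapply(scheme$behaviors, function(sig) {
    all(vapply(names(sig), function(nd) all(m[, nd] == sig[[nd]]), TRUE))
  }, TRUE)
  if (sum(matches) > 1L)
    stop("marker scheme is ambiguous: behaviors ",
         paste(names(matches)[matches], collapse = ", "),
         " all match this attractor", call. = FALSE)
  if (any(matches)) names(matches)[matches] else scheme$atypical
}

#' Check attractor validity against mutually exclusive groups
#'
#' Valid iff in every cycle state each group has exactly one true member
#' and every required component has at least one true node in every cycle
#' state.  Violations are reported with the group/component and the 1-based
#' cycle-state index.
#'
#' @param att a `bn_attractor`.
#' @param groups named list of character vectors: mutually exclusive node
#'   groups, members in stage order.
#' @param required_components optional named list of character vectors:
#'   components that must be represented (>= 1 true node) in every state.
#' @param nodes node names of the network.
#' @return list with `valid` (logical) and `violations` (data frame:
#'   `what`, `name`, `state`, `true_members`).
#' @export
check_validity <- function(att, groups, required_components = NULL, nodes) {
  all_named <- c(unlist(groups), unlist(required_components))
  unknown <- setdiff(all_named, nodes)
  if (length(unknown) > 0L)
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  m <- cycle_matrix(att, nodes)
  viol <- list()
  for (g in names(groups)) {
    cnt <- rowSums(m[, groups[[g]], drop = FALSE])
    for (s in which(cnt != 1L))
      viol[[length(viol) + 1L]] <- data.frame(
        what = "exclusive_group", name = g, state = s,
        true_members = cnt[s], stringsAsFactors = FALSE)
  }
  for (rc in names(required_components)) {
    cnt <- rowSums(m[, required_components[[rc]], drop = FALSE])
    for (s in which(cnt == 0L))
      viol[[length(viol) + 1L]] <- data.frame(
        what = "required_component", name = rc, state = s,
        true_members = 0L, stringsAsFactors = FALSE)
  }
  violations <- if (length(viol) > 0L) do.call(rbind, viol) else
    data.frame(what = character(0), name = character(0), state = integer(0),
               true_members = integer(0), stringsAsFactors = FALSE)
  list(valid = nrow(violations) == 0L, violations = violations)
}

#' Viability call for a valid attractor
#'
#' Viable iff the attractor is periodic and every stage of every macroscopic
#' process is true in at least one cycle state (all processes traversed);
#' point attractors and periodic attractors stuck in a stage are lethal.
#'
#' @inheritParams check_validity
#' @return `"viable"` or `"lethal"`.
#' @export
call_viability <- function(att, groups, nodes) {
  v <- check_validity(att, groups, nodes = nodes)
  if (!v$valid)
    stop("viability is defined only for valid attractors", call. = FALSE)
  if (att$period == 1L) return("lethal")
  m <- cycle_matrix(att, nodes)
  traversed <- all(vapply(groups, function(g)
    all(colSums(m[, g, drop = FALSE]) >= 1L), TRUE))
  if (traversed) "viable" else "lethal"
}

#' Components absent from an attractor relative to a reference
#'
#' A component is absent when all of its representing nodes are 0 in every
#' state of `att` while at least one of them is 1 somewhere in `ref` — the
#' bipartite-model signature of a de-facto deletion mutant.  Constitutively
#' zero nodes covered by no component are returned separately as a residue.
#'
#' @param att,ref `bn_attractor`s over the same network.
#' @param component_map named list of character vectors: component name ->
#'   nodes representing its states.
#' @param nodes node names of the network.
#' @return list with `absent` (character) and `residue` (character).
#' @export
absent_components <- function(att, ref, component_map, nodes) {
  unknown <- setdiff(unlist(component_map), nodes)
  if (length(unknown) > 0L)
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  ma <- cycle_matrix(att, nodes)
  mr <- cycle_matrix(ref, nodes)
  zero_att <- nodes[colSums(ma) == 0L]
  absent <- names(component_map)[vapply(component_map, function(nds)
    all(nds %in% zero_att) && any(colSums(mr[, nds, drop = FALSE]) > 0L), TRUE)]
  residue <- setdiff(zero_att, unlist(component_map))
  list(absent = absent, residue = residue)
}

#' Deduplicate attractors and tabulate a census
#'
#' Uniqueness is by canonical cycle identity (phase-independent).  When an
#' annotation function is supplied its label per unique attractor is added
#' and counted.
#'
#' @param attractors list of `bn_attractor`s (canonical).
#' @param annotate optional function(att) -> character label.
#' @return list with `unique` (deduplicated attractors, first-seen order)
#'   and `census` (data frame: `period`, optional `label`, `count`).
#' @export
dedupe_and_census <- function(attractors, annotate = NULL) {
  keys <- vapply(attractors, attractor_key, "")
  first <- !duplicated(keys)
  uniq <- attractors[first]
  periods <- vapply(uniq, function(a) a$period, 0L)
  if (is.null(annotate)) {
    census <- as.data.frame(table(period = periods), stringsAsFactors = FALSE)
    names(census) <- c("period", "count")
    census$period <- as.integer(census$period)
  } else {
    labels <- vapply(uniq, annotate, "")
    census <- as.data.frame(table(period = periods, label = labels),
                            stringsAsFactors = FALSE)
    names(census) <- c("period", "label", "count")
    census$period <- as.integer(census$period)
    census <- census[census$count > 0L, ]
    rownames(census) <- NULL
  }
  list(unique = uniq, census = census)
}

#' Read annotation configuration tables
#'
#' `read_groups`: TSV `group<TAB>node`, row order = stage order.
#' `read_markers`: TSV `behavior<TAB>node<TAB>value`.
#' `read_component_map`: TSV `component<TAB>node`.
#'
#' @param file path to the TSV file.
#' @return `read_groups`/`read_component_map`: named list of character
#'   vectors; `read_markers`: a [marker_scheme()].
#' @export
read_groups <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "node") %in% names(tab)))
  split(tab$node, factor(tab$group, levels = unique(tab$group)))
}

#' @rdname read_groups
#' @export
read_component_map <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("component", "node") %in% names(tab)))
  split(tab$node, factor(tab$component, levels = unique(tab$component)))
}

#' @rdname read_groups
#' @export
read_markers <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("behavior", "node", "value") %in% names(tab)))
  behaviors <- lapply(split(tab, factor(tab$behavior, levels = unique(tab$behavior))),
                      function(d) stats::setNames(as.integer(d$value), d$node))
  marker_scheme(behaviors)
}
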