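#' Water-wire endpoints
#'
#' A wire runs from a \emph{source} atom (e.g. a gating-glutamate
#' carboxylate oxygen, or an anion-pathway site) through hydrogen-bonded
#' waters to any water of the \emph{sink} (bulk intracellular solvent,
#' typically waters below the inner leaflet plane).  Source and sink must
#' resolve to disjoint atom sets.
#'
#' @param source,sink \code{clc_region} objects.
#' @return object of class \code{clc_wire_endpoints}.
#' @export
wire_endpoints <- function(source, sink) {
  structure(list(source = source, sink = sink),
            class = "clc_wire_endpoints")
}

#' Water-wire class definition
#'
#' Wires are sorted into three classes by route: class 1 connects the
#' intracellular solution to the anion permeation pathway, classes 2 and 3
#' to the gating glutamate in its "out" rotamer via distinct linings.  A
#' class is defined by the source variant it requires and a shell of lining
#' residues; a wire is assigned to the eligible class whose shell it
#' contacts most (deterministic tie-break: lowest class id).
#'
#' @param class_id 1, 2 or 3.
#' @param required_source \code{clc_region} the wire's source atom must
#'   belong to, or NULL for no constraint.
#' @param lining_shell \code{clc_region} of shell residues.
#' @param contact_radius wire-water / shell-atom contact distance,
#'   Angstrom (default 4).
#' @return object of class \code{clc_wire_class}.
#' @export
wire_class_def <- function(class_id, required_source = NULL, lining_shell,
                           contact_radius = 4.0) {
  stopifnot(class_id %in% 1:3, contact_radius > 0)
  structure(list(class_id = as.integer(class_id),
                 required_source = required_source,
                 lining_shell = lining_shell,
                 contact_radius = contact_radius),
            class = "clc_wire_class")
}

# BFS over the H-bond graph restricted to water-oxygen relays.
# Returns, for one source atom, the deterministic shortest path to the sink
# set (NULL when none): among minimum-hop sinks the smallest atom id wins,
# and the path is reconstructed choosing the smallest-id predecessor.
.bfs_wire <- function(adj, nodes, source_id, sink_ids, relay_ok) {
  n <- length(nodes)
  s <- match(source_id, nodes)
  dist <- rep(NA_integer_, n)
  dist[s] <- 0L
  queue <- s
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!is.na(dist[w])) next
      # only water oxygens (or sinks) may be entered as relays
      if (!relay_ok[w]) next
      dist[w] <- dist[v] + 1L
      queue <- c(queue, w)
    }
  }
  sk <- match(sink_ids, nodes)
  sk <- sk[!is.na(sk) & !is.na(dist[sk])]
  if (length(sk) == 0) return(NULL)
  dmin <- min(dist[sk])
  target <- min(nodes[sk[dist[sk] == dmin]])
  # backtrack picking smallest-id predecessor at each layer
  path <- integer(dmin + 1)
  cur <- match(target, nodes)
  path[dmin + 1] <- cur
  for (d in rev(seq_len(dmin))) {
    preds <- adj[[cur]]
    preds <- preds[!is.na(dist[preds]) & dist[preds] == d - 1L]
    preds <- preds[preds == s | relay_ok[preds]]
    cur <- preds[which.min(nodes[preds])]
    path[d] <- cur
  }
  nodes[path]
}

#' Find water wires in one frame
#'
#' Breadth-first (fewest-hop) search from every resolved source atom to the
#' sink set over the frame's hydrogen-bond graph.  Intermediate nodes are
#' water oxygens only; protein atoms act as endpoints, not relays (switch
#' with \code{allow_protein_relays}).  One deterministic shortest wire per
#' source atom, deduplicated on the node sequence.
#'
#' @param graph \code{clc_hbond_graph} for the frame.
#' @param endpoints \code{clc_wire_endpoints}.
#' @param frame n_atoms x 3 coordinates.
#' @param topology \code{clc_topology}.
#' @param membrane optional \code{clc_membrane} for z-based sinks.
#' @param allow_protein_relays if TRUE protein graph nodes may relay.
#' @param max_length optional cap on the number of waters in a wire.
#' @return list of \code{clc_wire} objects: list(frame_index, nodes,
#'   n_waters, class_label); empty list when no path exists.
#' @export
find_wires <- function(graph, endpoints, frame, topology, membrane = NULL,
                       allow_protein_relays = FALSE, max_length = Inf) {
  src <- resolve_region(endpoints$source, topology, frame, membrane)
  snk <- resolve_region(endpoints$sink, topology, frame, membrane)
  if (length(intersect(src, snk)) > 0)
    stop("wire endpoints overlap: source and sink share atoms")
  if (length(src) == 0 || length(snk) == 0) return(list())
  nodes <- graph$nodes
  src <- intersect(src, nodes)
  snk <- intersect(snk, nodes)
  if (length(src) == 0 || length(snk) == 0) return(list())
  n <- length(nodes)
  adj <- rep(list(integer(0)), n)
  if (nrow(graph$edges) > 0) {
    ei <- match(graph$edges$i, nodes)
    ej <- match(graph$edges$j, nodes)
    for (k in seq_along(ei)) {
      adj[[ei[k]]] <- c(adj[[ei[k]]], ej[k])
      adj[[ej[k]]] <- c(adj[[ej[k]]], ei[k])
    }
    adj <- lapply(adj, function(v) v[order(nodes[v])])
  }
  role <- topology$atoms$role[match(nodes, topology$atoms$atom_id)]
  relay_ok <- role == "water"
  if (allow_protein_relays) relay_ok <- relay_ok | role == "protein"
  relay_ok[match(snk, nodes)] <- TRUE
  wires <- list()
  seen <- character(0)
  for (s in src) {
    p <- .bfs_wire(adj, nodes, s, snk, relay_ok)
    if (is.null(p)) next
    nw <- length(p) - 1L          # waters: all nodes after the source
    if (nw > max_length) next
    key <- paste(p, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    wires[[length(wires) + 1]] <-
      structure(list(frame_index = graph$frame_index, nodes = p,
                     n_waters = nw, class_label = "unclassified"),
                class = "clc_wire")
  }
  wires
}

#' Classify a wire by its lining shell
#'
#' The wire is eligible for a class when its source atom belongs to the
#' class's required source (if any); among eligible classes the one whose
#' lining shell makes the most contacts with the wire's waters (within the
#' class contact radius) wins, ties going to the lowest class id.  A wire
#' contacting no shell is \code{"unclassified"}.
#'
#' @param wire \code{clc_wire}.
#' @param defs list of \code{clc_wire_class} covering classes 1-3.
#' @param frame n_atoms x 3 coordinates.
#' @param topology \code{clc_topology}.
#' @param membrane optional \code{clc_membrane}.
#' @return label: "1", "2", "3" or "unclassified".
#' @export
classify_wire <- function(wire, defs, frame, topology, membrane = NULL) {
  stopifnot(length(defs) >= 1)
  ids <- vapply(defs, function(d) d$class_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate class ids in defs")
  atom_rows <- match(wire$nodes, topology$atoms$atom_id)
  src_atom <- wire$nodes[1]
  waters <- wire$nodes[-1]
  wrows <- match(waters, topology$atoms$atom_id)
  wxyz <- frame[wrows, , drop = FALSE]
  best_class <- NA_integer_; best_contacts <- 0L
  for (d in defs[order(ids)]) {
    if (!is.null(d$required_source)) {
      req <- resolve_region(d$required_source, topology, frame, membrane)
      if (!(src_atom %in% req)) next
    }
    shell <- resolve_region(d$lining_shell, topology, frame, membrane)
    shell <- setdiff(shell, wire$nodes)
    if (length(shell) == 0) next
    srows <- match(shell, topology$atoms$atom_id)
    sxyz <- frame[srows, , drop = FALSE]
    contacts <- 0L
    for (w in seq_len(nrow(wxyz))) {
      d2 <- (sxyz[, 1] - wxyz[w, 1])^2 + (sxyz[, 2] - wxyz[w, 2])^2 +
        (sxyz[, 3] - wxyz[w, 3])^2
      if (any(d2 <= d$contact_radius^2)) contacts <- contacts + 1L
    }
    if (contacts > best_contacts) {
      best_contacts <- contacts
      best_class <- d$class_id
    }
  }
  if (is.na(best_class) || best_contacts == 0L) "unclassified"
  else as.character(best_class)
}

#' Fraction of frames containing at least one wire
#'
#' @param per_frame_wires list (one element per frame) of wire lists as
#'   returned by [find_wires()].
#' @return fraction in [0, 1].
#' @export
wire_fraction <- function(per_frame_wires) {
  if (length(per_frame_wires) == 0) stop("wire_fraction: zero frames")
  mean(vapply(per_frame_wires, function(w) length(w) > 0, logical(1)))
}

#' Box-plot summary across simulations
#'
#' Median and quartiles (linear-interpolation convention, R type 7) across
#' per-simulation values; whiskers extend to the last data points within
#' 1.5 x IQR of the quartiles, and points beyond are listed as outliers.
#'
#' @param fractions numeric vector, one value per simulation (length >= 2).
#' @return list(median, q1, q3, whisker_low, whisker_high, outliers, n).
#' @export
summarize_box <- function(fractions) {
  if (length(fractions) < 2)
    stop("summarize_box needs at least 2 simulations")
  q <- unname(stats::quantile(fractions, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- fractions[fractions >= lo_fence & fractions <= hi_fence]
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(fractions[fractions < lo_fence | fractions > hi_fence]),
       n = length(fractions))
}

#' Validate a wire against its frame's H-bond graph
#'
#' Independent re-check that every consecutive node pair of the wire is an
#' edge of the graph (used by tests and reports; not part of the search).
#'
#' @param wire \code{clc_wire}
#' @param graph \code{clc_hbond_graph}
#' @return TRUE/FALSE
#' @export
validate_wire <- function(wire, graph) {
  key <- paste(pmin(graph$edges$i, graph$edges$j),
               pmax(graph$edges$i, graph$edges$j))
  for (k in seq_len(length(wire$nodes) - 1)) {
    a <- wire$nodes[k]; b <- wire$nodes[k + 1]
    if (!(paste(min(a, b), max(a, b)) %in% key)) return(FALSE)
  }
  TRUE
}
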