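rmsd_fit <- function(a, b) kabsch(a, b)$rmsd

#' Leader-algorithm conformational clustering
#'
#' Single pass in time order: each frame joins the first leader (in creation
#' order) whose RMSD to the frame is below the cutoff, otherwise it becomes
#' a new leader. RMSD is computed over the selection after optimal proper
#' superposition onto the candidate leader (on roto-translation-removed
#' trajectories the superposition is nearly moot; it is kept for
#' robustness). Ties are impossible by construction: the first-created
#' leader within the cutoff always wins.
#'
#' @param traj a [trajectory()].
#' @param selection atom indices used for the RMSD (default all; Calpha for
#'   proteins is the convention).
#' @param cutoff RMSD cutoff in Angstrom (default 1.5).
#' @param stride frame stride (default 1).
#' @return Object of class `transition_network`: `leaders` (frame indices),
#'   `assignment` (per used frame), `occupancy`, `counts` (directed lag-1
#'   transition counts), `macrostate` (NA until [kinetic_network()]),
#'   `frames_used`.
#' @export
leader_cluster <- function(traj, selection = NULL, cutoff = 1.5, stride = 1) {
  stopifnot(inherits(traj, "traj"))
  if (cutoff <= 0) stop("cutoff must be positive")
  sel <- if (is.null(selection)) seq_len(traj$natoms) else selection
  frames <- seq(1, traj$nframes, by = stride)
  if (length(frames) == 0L) stop("empty trajectory")
  leaders <- integer(0)
  leader_coords <- list()
  assignment <- integer(length(frames))
  for (fi in seq_along(frames)) {
    fr <- matrix(traj$coords[frames[fi], sel, ], ncol = 3)
    hit <- 0L
    for (li in seq_along(leaders)) {
      if (rmsd_fit(fr, leader_coords[[li]]) < cutoff) { hit <- li; break }
    }
    if (hit == 0L) {
      leaders <- c(leaders, frames[fi])
      leader_coords[[length(leaders)]] <- fr
      hit <- length(leaders)
    }
    assignment[fi] <- hit
  }
  nl <- length(leaders)
  counts <- matrix(0L, nl, nl)
  if (length(assignment) > 1L)
    for (i in seq_len(length(assignment) - 1L))
      counts[assignment[i], assignment[i + 1L]] <-
        counts[assignment[i], assignment[i + 1L]] + 1L
  structure(list(leaders = leaders, leader_coords = leader_coords,
                 assignment = assignment,
                 occupancy = tabulate(assignment, nbins = nl),
                 counts = counts, macrostate = rep(NA_integer_, nl),
                 frames_used = frames, cutoff = cutoff),
            class = "transition_network")
}

#' @export
print.transition_network <- function(x, ...) {
  cat(sprintf("Transition network: %d leaders over %d frames (cutoff %g A)\n",
              length(x$leaders), length(x$assignment), x$cutoff))
  if (!all(is.na(x$macrostate)))
    cat(sprintf("  %d kinetic macrostates\n", length(unique(x$macrostate))))
  invisible(x)
}

#' Row-stochastic transition matrix of a network
#'
#' Normalizes the directed lag-1 interconversion counts between cluster
#' leaders row-wise; self-transitions are retained.
#'
#' @param net a [leader_cluster()] result.
#' @return Row-stochastic matrix (rows with no outgoing transitions get a
#'   self-loop of 1).
#' @export
transition_matrix <- function(net) {
  stopifnot(inherits(net, "transition_network"))
  P <- net$counts
  rs <- rowSums(P)
  for (i in seq_len(nrow(P))) {
    if (rs[i] == 0) P[i, i] <- 1 else P[i, ] <- P[i, ] / rs[i]
  }
  P
}

#' Markov clustering (MCL) of a transition matrix
#'
#' Standard MCL iteration on a stochastic matrix: expansion (matrix power),
#' inflation (elementwise power followed by renormalization), pruning of
#' entries below a threshold, repeated to convergence; macrostates are read
#' off the attractor structure of the limit matrix. Kinetically
#' interconverting leaders end up in the same macrostate.
#'
#' @param matrix row-stochastic transition matrix.
#' @param expansion integer matrix power (>= 2, default 2).
#' @param inflation elementwise power (> 1, default 1.8).
#' @param prune entries below this are zeroed each iteration (default 1e-6).
#' @param max_iter,tol iteration controls.
#' @return Integer vector of macrostate labels (1-based, by first
#'   occurrence).
#' @export
markov_cluster <- function(matrix, expansion = 2, inflation = 1.8,
                           prune = 1e-6, max_iter = 200, tol = 1e-10) {
  if (expansion < 2) stop("expansion must be >= 2")
  if (inflation <= 1) stop("inflation must be > 1")
  if (any(abs(rowSums(matrix) - 1) > 1e-8))
    stop("input must be row-stochastic")
  n <- nrow(matrix)
  if (n == 1L) return(1L)
  M <- t(matrix)                     # column-stochastic, MCL convention
  for (it in seq_len(max_iter)) {
    Mold <- M
    Me <- M
    for (e in seq_len(expansion - 1L)) Me <- Me %*% Mold
    M <- Me^inflation
    M[M < prune] <- 0
    cs <- colSums(M)
    cs[cs == 0] <- 1
    M <- sweep(M, 2, cs, "/")
    if (max(abs(M - Mold)) < tol) break
    if (it == max_iter)
      stop(sprintf("MCL did not converge in %d iterations (residual %.3g)",
                   max_iter, max(abs(M - Mold))))
  }
  # attractors: nodes with mass on their own diagonal
  attractors <- which(diag(M) > prune)
  if (length(attractors) == 0L) attractors <- which.max(diag(M))
  # node j belongs to attractor i when M[i, j] > 0; merge overlapping sets
  g_edges <- NULL
  for (i in attractors) {
    members <- which(M[i, ] > prune)
    g_edges <- rbind(g_edges, cbind(i, unique(c(i, members))))
  }
  g <- igraph::graph_from_edgelist(apply(g_edges, 2, as.character),
                                   directed = FALSE)
  g <- igraph::add_vertices(g,
                            length(setdiff(as.character(seq_len(n)),
                                           igraph::V(g)$name)),
                            name = setdiff(as.character(seq_len(n)),
                                           igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  lab <- comp[as.character(seq_len(n))]
  as.integer(factor(lab, levels = unique(lab)))
}

#' Attach kinetic macrostates to a network
#'
#' Runs [transition_matrix()] + [markov_cluster()] and stores the macrostate
#' labels on the network.
#'
#' @param net a [leader_cluster()] result.
#' @param ... passed to [markov_cluster()].
#' @return The network with `macrostate` filled in.
#' @export
kinetic_network <- function(net, ...) {
  net$macrostate <- markov_cluster(transition_matrix(net), ...)
  net
}

#' Export a transition network
#'
#' Writes the conformational/kinetic network for external visualization.
#' Node attributes: occupancy, macrostate; edge attributes: transition
#' counts and row-normalized probabilities. GraphML is written through
#' igraph; GEXF is written directly.
#'
#' @param net a `transition_network`.
#' @param path output file path.
#' @param format `"gexf"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("gexf", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "transition_network"))
  nl <- length(net$leaders)
  if (nl == 0L) stop("empty network")
  P <- transition_matrix(net)
  ed <- which(net$counts > 0, arr.ind = TRUE)
  macro <- ifelse(is.na(net$macrostate), 0L, net$macrostate)
  if (format == "graphml") {
    g <- igraph::make_empty_graph(n = nl, directed = TRUE)
    igraph::V(g)$name <- as.character(seq_len(nl))
    igraph::V(g)$occupancy <- net$occupancy
    igraph::V(g)$macrostate <- macro
    if (nrow(ed) > 0) {
      g <- igraph::add_edges(g, t(ed))
      igraph::E(g)$count <- net$counts[ed]
      igraph::E(g)$probability <- P[ed]
    }
    igraph::write_graph(g, path, format = "graphml")
  } else {
    doc <- xml2::xml_new_root("gexf",
                              xmlns = "http://www.gexf.net/1.2draft",
                              version = "1.2")
    graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "directed")
    attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
    xml2::xml_add_child(attrs, "attribute", id = "0", title = "occupancy",
                        type = "integer")
    xml2::xml_add_child(attrs, "attribute", id = "1", title = "macrostate",
                        type = "integer")
    eattrs <- xml2::xml_add_child(graph, "attributes", class = "edge")
    xml2::xml_add_child(eattrs, "attribute", id = "2", title = "count",
                        type = "integer")
    xml2::xml_add_child(eattrs, "attribute", id = "3", title = "probability",
                        type = "double")
    nodes <- xml2::xml_add_child(graph, "nodes")
    for (i in seq_len(nl)) {
      nd <- xml2::xml_add_child(nodes, "node", id = as.character(i),
                                label = sprintf("leader_%d", i))
      av <- xml2::xml_add_child(nd, "attvalues")
      xml2::xml_add_child(av, "attvalue", "for" = "0",
                          value = as.character(net$occupancy[i]))
      xml2::xml_add_child(av, "attvalue", "for" = "1",
                          value = as.character(macro[i]))
    }
    edges <- xml2::xml_add_child(graph, "edges")
    if (nrow(ed) > 0) for (k in seq_len(nrow(ed))) {
      eg <- xml2::xml_add_child(edges, "edge", id = as.character(k),
                                source = as.character(ed[k, 1]),
                                target = as.character(ed[k, 2]))
      av <- xml2::xml_add_child(eg, "attvalues")
      xml2::xml_add_child(av, "attvalue", "for" = "2",
                          value = as.character(net$counts[ed[k, , drop = FALSE]]))
      xml2::xml_add_child(av, "attvalue", "for" = "3",
                          value = as.character(P[ed[k, , drop = FALSE]]))
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Write frame assignments as CSV
#' @param net a `transition_network`.
#' @param file output path; columns `frame`, `leader`, `macrostate`.
#' @return `file`, invisibly.
#' @export
write_assignment_csv <- function(net, file) {
  write.csv(data.frame(frame = net$frames_used,
                       leader = net$assignment,
                       macrostate = net$macrostate[net$assignment]),
            file, row.names = FALSE)
  invisible(file)
}
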