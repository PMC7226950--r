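# Residue-contact network analysis.
#
# Residues are nodes; an undirected edge joins two residues whose C-alpha
# atoms lie strictly closer than the cutoff (default 0.6 nm, i.e. 6 A).
# Per-residue degree and (component-scaled) closeness centrality are
# accumulated over a sample of ~100 frames to give per-residue
# distributions. Shortest paths are delegated to igraph.

# Rows of the C-alpha atoms (one per residue) for the given selection.
.ca_rows <- function(top, sel = NULL) {
  rows <- sel_rows(top, sel)
  at <- top$atoms[rows, ]
  ca <- rows[at$name == "CA"]
  if (!length(ca)) ca <- rows  # C-alpha-only fixtures name everything CA
  at <- top$atoms[ca, ]
  key <- paste(at$chain, at$resno, at$insert)
  dup <- duplicated(key)
  if (any(dup))
    stop("residue ", key[which(dup)[1]], " has more than one C-alpha")
  ca
}

#' Build a residue-contact graph from one frame
#'
#' @param frame \code{N x 3} coordinate matrix (nm).
#' @param top the \code{topology} the frame belongs to.
#' @param sel selection of residues to include (via their C-alpha atoms);
#'   NULL = all.
#' @param cutoff contact cutoff (nm); an edge requires distance strictly
#'   below it (default 0.6 nm).
#' @return object of class \code{"contact_graph"}: list with \code{graph}
#'   (igraph), \code{labels} (residue labels "chain:resno"), \code{cutoff}.
#' @export
build_contact_graph <- function(frame, top, sel = NULL, cutoff = 0.6) {
  ca <- .ca_rows(top, sel)
  xyz <- frame[ca, , drop = FALSE]
  at <- top$atoms[ca, ]
  labels <- paste0(at$chain, ":", at$resno,
                   ifelse(at$insert == "" | is.na(at$insert), "", at$insert))
  d <- as.matrix(stats::dist(xyz))
  adj <- d < cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- labels
  structure(list(graph = g, labels = labels, cutoff = cutoff),
            class = "contact_graph")
}

#' Per-residue degree of a contact graph
#' @param cg a \code{contact_graph}.
#' @return named integer vector (number of contacting residues).
#' @export
node_degree <- function(cg) {
  d <- igraph::degree(cg$graph)
  stats::setNames(as.integer(d), cg$labels)
}

#' Component-scaled closeness centrality
#'
#' For a node v in a connected component of size \code{n_c} within a graph
#' of \code{n} nodes, closeness is
#' \code{((n_c - 1) / (n - 1)) * (n_c - 1) / sum_u d(v, u)} (Wasserman-Faust
#' scaling over the reachable set), which keeps values in [0, 1] and
#' comparable across frames even when the contact graph disconnects.
#' Isolated nodes score 0.
#'
#' @param cg a \code{contact_graph}.
#' @return named numeric vector in [0, 1].
#' @export
closeness_centrality <- function(cg) {
  g <- cg$graph
  n <- igraph::vcount(g)
  out <- numeric(n)
  if (n > 1L) {
    D <- igraph::distances(g)
    for (v in seq_len(n)) {
      dv <- D[v, -v]
      reach <- is.finite(dv)
      nc <- sum(reach) + 1L
      if (nc > 1L)
        out[v] <- ((nc - 1) / (n - 1)) * (nc - 1) / sum(dv[reach])
    }
  }
  stats::setNames(out, cg$labels)
}

#' Degree and closeness distributions over sampled frames
#'
#' Builds a contact graph on each of ~\code{sample_n} frames (evenly spaced
#' by default, or uniform random with a seed) and accumulates per-residue
#' metric values, the long-format input for per-residue boxplots.
#'
#' @param ens an \code{ensemble}.
#' @param sel residue selection (C-alpha atoms), NULL = all.
#' @param sample_n number of frames to sample (default 100, capped at the
#'   frame count).
#' @param cutoff contact cutoff (nm).
#' @param sampling \code{"even"} (deterministic) or \code{"random"}.
#' @param seed RNG seed for random sampling.
#' @return data.frame with columns \code{residue}, \code{frame},
#'   \code{metric} ("degree" or "closeness"), \code{value}.
#' @export
metric_distributions <- function(ens, sel = NULL, sample_n = 100L,
                                 cutoff = 0.6,
                                 sampling = c("even", "random"),
                                 seed = 1L) {
  sampling <- match.arg(sampling)
  nt <- n_frames(ens)
  sample_n <- min(sample_n, nt)
  idx <- if (sampling == "even") {
    unique(round(seq(1, nt, length.out = sample_n)))
  } else {
    set.seed(seed)
    sort(sample.int(nt, sample_n))
  }
  res <- vector("list", 2L * length(idx))
  k <- 0L
  for (t in idx) {
    cg <- build_contact_graph(get_frame(ens, t), ens$topology,
                              sel = sel, cutoff = cutoff)
    deg <- node_degree(cg)
    clo <- closeness_centrality(cg)
    k <- k + 1L
    res[[k]] <- data.frame(residue = names(deg), frame = t,
                           metric = "degree", value = as.numeric(deg))
    k <- k + 1L
    res[[k]] <- data.frame(residue = names(clo), frame = t,
                           metric = "closeness", value = as.numeric(clo))
  }
  do.call(rbind, res)
}

#' Quartile summary of metric distributions (boxplot statistics)
#'
#' @param dist long-format data.frame from
#'   \code{\link{metric_distributions}}.
#' @return data.frame with median and quartiles per residue and metric.
#' @export
metric_summary <- function(dist) {
  agg <- stats::aggregate(value ~ residue + metric, data = dist,
                          FUN = function(v)
                            c(q1 = unname(stats::quantile(v, 0.25)),
                              median = stats::median(v),
                              q3 = unname(stats::quantile(v, 0.75))))
  out <- data.frame(residue = agg$residue, metric = agg$metric,
                    q1 = agg$value[, "q1"], median = agg$value[, "median"],
                    q3 = agg$value[, "q3"])
  out[order(out$metric, out$residue), ]
}
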