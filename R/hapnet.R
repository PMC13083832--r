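#' Collapse phased haplotypes into unique sequence classes
#'
#' Merges identical haplotype columns and tallies, per unique haplotype, a
#' composition over sample labels (taxon, diplotype group, ...). Multiallelic
#' sites are one-hot encoded into binary columns first, which is also the
#' encoding the median-joining step operates on.
#'
#' @param h A phased [hap_matrix()] with no missing alleles.
#' @param labels Character vector of labels, either one per sample (applied
#'   to both haplotypes) or one per haplotype column.
#' @return A `collapsed_haps` list: `haps` (unique haplotypes x binary sites
#'   matrix), `count`, `composition` (list of named label counts), `key`
#'   (haplotype string keys).
#' @export
collapse_haplotypes <- function(h, labels = NULL) {
  stopifnot(inherits(h, "hap_matrix"))
  if (any(h$haps < 0L)) {
    stop("haplotypes contain missing alleles; mask those sites first",
         call. = FALSE)
  }
  nh <- ncol(h$haps)
  if (is.null(labels)) labels <- rep("all", nh)
  if (length(labels) == length(h$samples)) labels <- rep(labels, each = 2L)
  stopifnot(length(labels) == nh)
  enc <- one_hot_sites(h) # haplotypes x binary sites
  key <- apply(enc, 1, paste, collapse = "")
  ord <- order(key)
  uk <- unique(key[ord])
  idx <- split(seq_len(nh), factor(key, levels = uk))
  haps <- enc[vapply(idx, `[`, integer(1), 1L), , drop = FALSE]
  rownames(haps) <- NULL
  structure(
    list(haps = haps,
         count = lengths(idx),
         composition = lapply(idx, function(i) table(labels[i])),
         key = uk),
    class = "collapsed_haps")
}

# hap_matrix -> haplotypes x binary-site matrix; biallelic sites map to one
# 0/1 column, multiallelic sites to one indicator column per allele.
one_hot_sites <- function(h) {
  cols <- list()
  for (i in seq_len(nrow(h$variants))) {
    n_allele <- 1L + length(h$variants$alts[[i]])
    if (n_allele == 2L) {
      cols[[length(cols) + 1L]] <- h$haps[i, ]
    } else {
      for (a in 0:(n_allele - 1L)) {
        cols[[length(cols) + 1L]] <- as.integer(h$haps[i, ] == a)
      }
    }
  }
  m <- do.call(cbind, cols)
  storage.mode(m) <- "integer"
  m
}

#' Median-joining haplotype network
#'
#' Iterates the classic construction: (1) build the epsilon-relaxed minimum
#' spanning network over the current node set under Hamming distance — an
#' edge `(u, v)` is included when `d(u, v)` is within `epsilon` of the
#' distance at which the components of `u` and `v` first connect; (2) for
#' every connected triplet (a path `u - v - w`), form the site-wise majority
#' median vector; (3) add the novel medians and repeat until none appear or
#' `max_rounds` is hit. Median (Steiner) nodes not lying on any shortest path
#' between observed haplotypes are pruned at the end and the network rebuilt.
#' Ties in network construction are broken by lexicographic haplotype key, so
#' the result is deterministic and invariant to input order.
#'
#' @param x A `collapsed_haps` object (or a binary matrix with one row per
#'   unique haplotype).
#' @param epsilon Non-negative integer relaxation of the spanning network.
#' @param max_rounds Maximum median-addition rounds.
#' @return A `haplotype_network`: `nodes` (tibble `id`, `key`, `count`,
#'   `is_median`, `composition` list-column), `edges` (tibble `from`, `to`,
#'   `weight`), `haps` (node x site matrix), `epsilon`, `converged`.
#' @export
median_joining <- function(x, epsilon = 0, max_rounds = 20) {
  if (inherits(x, "collapsed_haps")) {
    haps <- x$haps
    count <- x$count
    comp <- x$composition
  } else {
    haps <- as.matrix(x)
    count <- rep(1L, nrow(haps))
    comp <- rep(list(table(character())), nrow(haps))
  }
  stopifnot(nrow(haps) >= 1L, epsilon >= 0)
  n_obs <- nrow(haps)
  is_median <- rep(FALSE, n_obs)

  converged <- TRUE
  if (nrow(haps) > 1L) {
    for (round in seq_len(max_rounds)) {
      edges <- msn_edges(haps, epsilon)
      med <- candidate_medians(haps, edges)
      if (nrow(med) == 0L) break
      haps <- rbind(haps, med)
      is_median <- c(is_median, rep(TRUE, nrow(med)))
      if (round == max_rounds) {
        converged <- FALSE
        warning("median-joining did not converge in ", max_rounds,
                " rounds", call. = FALSE)
      }
    }
    edges <- msn_edges(haps, epsilon)
    keep <- prune_medians(haps, edges, is_median)
    haps <- haps[keep, , drop = FALSE]
    is_median <- is_median[keep]
    edges <- msn_edges(haps, epsilon)
  } else {
    edges <- tibble::tibble(from = integer(), to = integer(),
                            weight = integer())
  }

  key <- apply(haps, 1, paste, collapse = "")
  count_full <- c(count, rep(0L, nrow(haps) - n_obs))[seq_len(nrow(haps))]
  comp_full <- c(comp, rep(list(table(character())),
                           max(0L, nrow(haps) - n_obs)))[seq_len(nrow(haps))]
  structure(
    list(nodes = tibble::tibble(id = seq_len(nrow(haps)), key = key,
                                count = as.integer(count_full),
                                is_median = is_median,
                                composition = comp_full),
         edges = edges, haps = haps, epsilon = epsilon,
         converged = converged),
    class = "haplotype_network")
}

# epsilon-relaxed minimum spanning network over Hamming distances.
# Edge kept iff d(u,v) <= connection_height(u,v) + epsilon, where the
# connection height is the single-linkage merge level (the distance at which
# the two nodes' components first join).
msn_edges <- function(haps, epsilon) {
  n <- nrow(haps)
  if (n < 2L) {
    return(tibble::tibble(from = integer(), to = integer(),
                          weight = integer()))
  }
  d <- hamming_matrix(haps)
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  ch <- as.matrix(stats::cophenetic(hc))
  keep <- which(upper.tri(d) & d <= ch + epsilon + 1e-9, arr.ind = TRUE)
  ord <- order(keep[, 1], keep[, 2])
  tibble::tibble(from = keep[ord, 1], to = keep[ord, 2],
                 weight = as.integer(d[keep[ord, , drop = FALSE]]))
}

hamming_matrix <- function(haps) {
  n <- nrow(haps)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(haps[i, ] != haps[j, ])
    }
  }
  d
}

# Site-wise majority vectors of all connected triplets (paths u - v - w),
# deduplicated against existing haplotypes and each other; returned in
# lexicographic key order for determinism.
candidate_medians <- function(haps, edges) {
  if (nrow(edges) == 0L) return(haps[0, , drop = FALSE])
  adj <- split(c(edges$to, edges$from), c(edges$from, edges$to))
  have <- apply(haps, 1, paste, collapse = "")
  med <- list()
  for (v in as.integer(names(adj))) {
    nb <- sort(unique(adj[[as.character(v)]]))
    if (length(nb) < 2L) next
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a >= b) next
        trio <- haps[c(nb[a], v, nb[b]), , drop = FALSE]
        m <- as.integer(colSums(trio) >= 2L)
        k <- paste(m, collapse = "")
        if (!(k %in% have)) {
          med[[k]] <- m
          have <- c(have, k)
        }
      }
    }
  }
  if (!length(med)) return(haps[0, , drop = FALSE])
  out <- do.call(rbind, med[order(names(med))])
  rownames(out) <- NULL
  out
}

# Keep observed nodes always; keep a median node only when it lies on a
# shortest path between two observed nodes in the weighted network.
prune_medians <- function(haps, edges, is_median) {
  n <- nrow(haps)
  keep <- !is_median
  med_idx <- which(is_median)
  if (!length(med_idx) || nrow(edges) == 0L) return(keep)
  gr <- igraph::graph_from_data_frame(
    data.frame(from = edges$from, to = edges$to, weight = edges$weight),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  dm <- igraph::distances(gr, weights = igraph::E(gr)$weight)
  obs <- which(!is_median)
  for (m in med_idx) {
    on_path <- FALSE
    for (a in obs) {
      for (b in obs) {
        if (a >= b) next
        if (is.finite(dm[a, b]) &&
            abs(dm[a, m] + dm[m, b] - dm[a, b]) < 1e-9) {
          on_path <- TRUE
          break
        }
      }
      if (on_path) break
    }
    keep[m] <- on_path
  }
  keep
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("<haplotype_network> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$is_median), " median), ", nrow(x$edges),
      " edges, epsilon = ", x$epsilon, "\n", sep = "")
  invisible(x)
}

#' Shared haplotype nodes
#'
#' Nodes whose composition spans at least two distinct labels — the
#' "haplotype sharing" readout between taxa or diplotype groups.
#'
#' @param net A `haplotype_network`.
#' @return Tibble of shared nodes (`id`, `count`, `labels`).
#' @export
shared_nodes <- function(net) {
  sel <- vapply(net$nodes$composition, function(tb) sum(tb > 0) >= 2L,
                logical(1))
  tibble::tibble(
    id = net$nodes$id[sel],
    count = net$nodes$count[sel],
    labels = vapply(net$nodes$composition[sel],
                    function(tb) paste(names(tb)[tb > 0], collapse = ","),
                    character(1)))
}

#' Export a haplotype network to DOT or GraphML
#'
#' Nodes carry their observed count (size), median flag and composition
#' (fill proportions; uniform when empty); node order is deterministic
#' (by id, which follows haplotype key order within each construction
#' round).
#'
#' @param net A `haplotype_network`.
#' @param path Output path.
#' @param format `"dot"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("dot", "graphml")) {
  format <- match.arg(format)
  comp_str <- vapply(net$nodes$composition, function(tb) {
    if (!length(tb) || sum(tb) == 0) return("uniform")
    paste(sprintf("%s:%.4f", names(tb), as.numeric(tb) / sum(tb)),
          collapse = ";")
  }, character(1))
  if (format == "dot") {
    lines <- c("graph hapnet {", "  node [shape=circle];")
    for (i in seq_len(nrow(net$nodes))) {
      lines <- c(lines, sprintf(
        "  n%d [count=%d, median=%s, composition=\"%s\"];",
        net$nodes$id[i], net$nodes$count[i],
        ifelse(net$nodes$is_median[i], "true", "false"), comp_str[i]))
    }
    for (i in seq_len(nrow(net$edges))) {
      lines <- c(lines, sprintf("  n%d -- n%d [weight=%d];",
                                net$edges$from[i], net$edges$to[i],
                                net$edges$weight[i]))
    }
    lines <- c(lines, "}")
    writeLines(lines, path)
  } else {
    gr <- as_igraph(net)
    igraph::write_graph(gr, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a haplotype network to an igraph object
#'
#' @param net A `haplotype_network`.
#' @return An undirected `igraph` graph with node attributes `count`,
#'   `is_median`, `composition` and edge attribute `weight`.
#' @export
as_igraph <- function(net) {
  comp_str <- vapply(net$nodes$composition, function(tb) {
    if (!length(tb)) return("")
    paste(sprintf("%s:%d", names(tb), as.integer(tb)), collapse = ";")
  }, character(1))
  igraph::graph_from_data_frame(
    data.frame(from = paste0("n", net$edges$from),
               to = paste0("n", net$edges$to),
               weight = net$edges$weight),
    directed = FALSE,
    vertices = data.frame(name = paste0("n", net$nodes$id),
                          count = net$nodes$count,
                          is_median = net$nodes$is_median,
                          composition = comp_str))
}
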