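# Native HDBSCAN implementation: hierarchical density-based clustering
# over the mutual-reachability graph, with condensed-tree cluster
# selection (excess-of-mass or leaf) and the epsilon refinement that
# merges clusters separating below a distance threshold. Exact O(n^2)
# computations throughout — appropriate for repertoire-scale inputs
# (hundreds to a few thousand vocalisations).

#' @rdname cluster_hdbscan
#' @param x Numeric matrix of points (rows).
#' @export
hdbscan_labels <- function(x, min_cluster_size = 10L, min_samples = 3L,
                           epsilon = 0, selection = c("leaf", "eom")) {
  selection <- match.arg(selection)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < max(2L, min_cluster_size)) return(rep(-1L, n))

  # pairwise distances and core distances: distance to the min_samples-th
  # nearest *other* point, matching the reference implementations
  d <- as.matrix(stats::dist(x))
  k <- min(min_samples + 1L, n)
  core <- apply(d, 1, function(row) sort(row, partial = k)[k])
  mreach <- pmax(d, outer(core, core, pmax))
  diag(mreach) <- 0

  mst <- prim_mst(mreach)
  sl <- single_linkage(mst$from, mst$to, mst$weight, n)
  ct <- condense_tree(sl, n, min_cluster_size)
  if (nrow(ct$clusters) == 0) return(rep(-1L, n))  # no split survived
  selected <- select_clusters(ct, selection, epsilon)
  label_points(ct, selected, n)
}

# exact Prim MST on a dense distance matrix; returns n-1 edges
prim_mst <- function(w, n = nrow(w)) {
  in_tree <- logical(n)
  best <- rep(Inf, n)
  parent <- integer(n)
  from <- to <- integer(n - 1L)
  weight <- numeric(n - 1L)
  cur <- 1L
  in_tree[1L] <- TRUE
  for (e in seq_len(n - 1L)) {
    upd <- !in_tree & w[cur, ] < best
    best[upd] <- w[cur, upd]
    parent[upd] <- cur
    nxt <- which.min(ifelse(in_tree, Inf, best))
    from[e] <- parent[nxt]
    to[e] <- nxt
    weight[e] <- best[nxt]
    in_tree[nxt] <- TRUE
    cur <- nxt
  }
  list(from = from, to = to, weight = weight)
}

# single-linkage dendrogram from MST edges, scipy-linkage style:
# internal node i (1-based row) merges ids a, b at height h into id n+i;
# sizes track leaf counts
single_linkage <- function(from, to, weight, n) {
  ord <- order(weight)
  parent <- seq_len(2L * n - 1L)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  sizes <- c(rep(1L, n), integer(n - 1L))
  for (e in seq_len(n - 1L)) {
    i <- ord[e]
    a <- find(from[i]); b <- find(to[i])
    node <- n + e
    merges[e, ] <- c(a, b)
    heights[e] <- weight[i]
    sizes[node] <- sizes[a] + sizes[b]
    parent[a] <- node
    parent[b] <- node
  }
  list(merges = merges, heights = heights, sizes = sizes)
}

# condensed tree: walk the dendrogram top-down; a split is real when both
# sides keep >= min_cluster_size points, otherwise the small side's
# points fall out of the current cluster at that level's lambda = 1/d.
# Returns per-point fall-out rows and a cluster-node table.
condense_tree <- function(sl, n, min_cluster_size) {
  n_nodes <- n - 1L
  point_cluster <- integer(n)    # condensed cluster each point fell from
  point_lambda <- numeric(n)
  cl_parent <- integer(0)        # condensed cluster table
  cl_birth <- numeric(0)         # lambda at which the cluster appeared
  cl_size <- integer(0)
  cl_death <- numeric(0)         # lambda at which it split (Inf if leaf)

  new_cluster <- function(parent, birth, size) {
    cl_parent[length(cl_parent) + 1L] <<- parent
    cl_birth[length(cl_birth) + 1L] <<- birth
    cl_size[length(cl_size) + 1L] <<- size
    cl_death[length(cl_death) + 1L] <<- Inf
    length(cl_parent)
  }
  root <- new_cluster(0L, 0, n)

  # leaves under a dendrogram id, iteratively
  leaves_under <- function(id) {
    out <- integer(0)
    stack <- id
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (i <= n) out[length(out) + 1L] <- i
      else stack <- c(stack, sl$merges[i - n, ])
    }
    out
  }

  # iterative top-down walk: (dendrogram id, condensed cluster id)
  stack_id <- 2L * n - 1L
  stack_cl <- root
  while (length(stack_id)) {
    id <- stack_id[length(stack_id)]; stack_id <- stack_id[-length(stack_id)]
    cl <- stack_cl[length(stack_cl)]; stack_cl <- stack_cl[-length(stack_cl)]
    if (id <= n) {  # singleton reached without falling out: lambda = Inf
      point_cluster[id] <- cl
      point_lambda[id] <- Inf
      next
    }
    row <- id - n
    lam <- if (sl$heights[row] > 0) 1 / sl$heights[row] else Inf
    kids <- sl$merges[row, ]
    sz <- ifelse(kids <= n, 1L, sl$sizes[kids])
    big <- sz >= min_cluster_size
    if (all(big)) {
      cl_death[cl] <- lam
      for (kid in kids) {
        child <- new_cluster(cl, lam, sl$sizes[kid])
        stack_id <- c(stack_id, kid)
        stack_cl <- c(stack_cl, child)
      }
    } else if (any(big)) {
      # cluster continues through the big side; small side falls out
      small <- kids[!big]
      for (p in leaves_under(small)) {
        point_cluster[p] <- cl
        point_lambda[p] <- lam
      }
      stack_id <- c(stack_id, kids[big])
      stack_cl <- c(stack_cl, cl)
    } else {
      # both sides too small: everything falls out here
      for (p in leaves_under(id)) {
        point_cluster[p] <- cl
        point_lambda[p] <- lam
      }
    }
  }
  list(points = data.frame(cluster = point_cluster, lambda = point_lambda),
       clusters = data.frame(id = seq_along(cl_parent), parent = cl_parent,
                             birth = cl_birth, death = cl_death,
                             size = cl_size))
}

# stability of each condensed cluster: sum over its own fall-out events
# (points and child clusters) of (lambda_event - lambda_birth)
cluster_stability <- function(ct) {
  cl <- ct$clusters
  stab <- numeric(nrow(cl))
  pts <- ct$points
  cap <- ifelse(is.finite(cl$death[pts$cluster]), cl$death[pts$cluster],
                NA)
  lam <- ifelse(is.finite(pts$lambda), pts$lambda,
                ifelse(is.na(cap), max(pts$lambda[is.finite(pts$lambda)],
                                       1), cap))
  for (i in seq_len(nrow(pts))) {
    c_ <- pts$cluster[i]
    stab[c_] <- stab[c_] + (lam[i] - cl$birth[c_])
  }
  kids <- which(cl$parent > 0)
  for (k in kids) {
    p <- cl$parent[k]
    stab[p] <- stab[p] + cl$size[k] * (cl$birth[k] - cl$birth[p])
  }
  stab
}

select_clusters <- function(ct, selection, epsilon) {
  cl <- ct$clusters
  has_child <- cl$id %in% cl$parent
  if (selection == "leaf") {
    selected <- cl$id[!has_child & cl$parent > 0]  # never the root
    if (length(selected) == 0) return(integer(0))
  } else {
    stab <- cluster_stability(ct)
    selected_flag <- !has_child                     # leaves start selected
    # bottom-up excess-of-mass: process deepest first
    depth <- integer(nrow(cl))
    for (i in cl$id) {
      p <- cl$parent[i]
      depth[i] <- if (p == 0) 0L else depth[p] + 1L
    }
    for (i in cl$id[order(depth, decreasing = TRUE)]) {
      if (!has_child[i] || i == 1L) next  # the root is never a candidate
      kids <- cl$id[cl$parent == i]
      child_sum <- sum(stab[kids])
      if (stab[i] < child_sum) {
        stab[i] <- child_sum
        selected_flag[i] <- FALSE
      } else {
        selected_flag[i] <- TRUE
        # deselect the whole subtree
        sub <- kids
        while (length(sub)) {
          selected_flag[sub] <- FALSE
          sub <- cl$id[cl$parent %in% sub]
        }
      }
    }
    selected_flag[1L] <- FALSE                      # root excluded
    selected <- cl$id[selected_flag]
  }
  if (epsilon > 0) {
    selected <- epsilon_search(ct, selected, epsilon)
  }
  sort(unique(selected))
}

# merge clusters that separated below the epsilon distance: replace each
# selected cluster born at distance < epsilon by its lowest ancestor born
# at distance >= epsilon (stopping below the root)
epsilon_search <- function(ct, selected, epsilon) {
  cl <- ct$clusters
  processed <- logical(nrow(cl))
  out <- integer(0)
  for (s in selected) {
    if (processed[s]) next
    birth_dist <- 1 / cl$birth[s]
    if (cl$birth[s] > 0 && birth_dist < epsilon) {
      node <- s
      repeat {
        p <- cl$parent[node]
        if (p == 0) break                     # node is the root: stop
        if (cl$parent[p] == 0) break          # parent is root: keep node
        if (1 / cl$birth[p] >= epsilon) { node <- p; break }
        node <- p
      }
      out <- c(out, node)
      # mark the subtree handled
      sub <- node
      while (length(sub)) {
        processed[sub] <- TRUE
        sub <- cl$id[cl$parent %in% sub]
      }
    } else {
      out <- c(out, s)
      processed[s] <- TRUE
    }
  }
  out
}

label_points <- function(ct, selected, n) {
  if (length(selected) == 0) return(rep(-1L, n))
  cl <- ct$clusters
  # map every condensed cluster to its selected ancestor (or 0)
  owner <- integer(nrow(cl))
  for (i in cl$id) {
    node <- i
    while (node != 0 && !(node %in% selected)) node <- cl$parent[node]
    owner[i] <- if (node == 0) 0L else node
  }
  labels_map <- stats::setNames(seq_along(selected) - 1L, selected)
  out <- rep(-1L, n)
  own <- owner[ct$points$cluster]
  hit <- own > 0
  out[hit] <- labels_map[as.character(own[hit])]
  out
}
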