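#' Detection parameters for cohesiveness-based module growth
#'
#' Bundles the free parameters of the greedy cohesiveness clustering.
#' \code{penalty} is the per-node term in the cohesiveness denominator and
#' models unobserved edges to the rest of the system; \code{minSize} and
#' \code{minDensity} discard trivially small or sparse grown clusters;
#' \code{mergeOverlapOmega} is the match-coefficient threshold
#' \eqn{\omega(A,B) = |A \cap B|^2 / (|A| |B|)} above which grown clusters
#' are unioned at detection time.  Defaults follow the published defaults of
#' the cohesiveness-based clustering algorithm.
#'
#' @param penalty per-node penalty, >= 0 (default 2).
#' @param minSize minimum module size, >= 2 (default 3).
#' @param minDensity minimum internal edge density in [0, 1] (default 0.3).
#' @param mergeOverlapOmega match-coefficient merge threshold in (0, 1]
#'   (default 0.8).
#' @return a list of class \code{"DetectionParams"}.
#' @export
detectionParams <- function(penalty = 2, minSize = 3L, minDensity = 0.3,
                            mergeOverlapOmega = 0.8) {
  stopifnot(penalty >= 0, minSize >= 2L, minDensity >= 0, minDensity <= 1,
            mergeOverlapOmega > 0, mergeOverlapOmega <= 1)
  structure(list(penalty = penalty, minSize = as.integer(minSize),
                 minDensity = minDensity,
                 mergeOverlapOmega = mergeOverlapOmega,
                 seedOrder = "degree_desc"),
            class = "DetectionParams")
}

# locale-independent ordering of gene ids, so tie-breaks are reproducible
.strOrder <- function(x) order(x, method = "radix")

# adjacency lists + strengths for fast incremental cohesiveness updates
.adjacency <- function(network) {
  g <- network@graph
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- if (igraph::ecount(g)) igraph::E(g)$weight else numeric()
  adj <- vector("list", n)
  adjw <- vector("list", n)
  if (nrow(el)) {
    ends <- c(el[, 1L], el[, 2L])
    other <- c(el[, 2L], el[, 1L])
    ww <- c(w, w)
    o <- order(ends)
    ends <- ends[o]; other <- other[o]; ww <- ww[o]
    idx <- split(seq_along(ends), factor(ends, levels = seq_len(n)))
    for (i in seq_len(n)) {
      adj[[i]] <- other[idx[[i]]]
      adjw[[i]] <- ww[idx[[i]]]
    }
  } else {
    for (i in seq_len(n)) { adj[[i]] <- integer(); adjw[[i]] <- numeric() }
  }
  list(n = n, names = nm, adj = adj, adjw = adjw,
       strength = vapply(adjw, sum, 0),
       degree = lengths(adj))
}

#' Cohesiveness of a gene set in a coexpression network
#'
#' The quality score maximized by module growth:
#' \deqn{f(V) = \frac{w_{in}(V)}{w_{in}(V) + w_{bound}(V) + p |V|}}
#' where \eqn{w_{in}} is the total weight of edges with both ends in
#' \eqn{V}, \eqn{w_{bound}} the total weight of edges with exactly one end in
#' \eqn{V}, and \eqn{p} the per-node penalty.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param genes character vector of gene ids, all present in the network.
#' @param penalty per-node penalty \eqn{p} (default 2).
#' @return cohesiveness in [0, 1].
#' @examples
#' # unit-weight triangle: f(all three) = 3/3 = 1; f(two) = 1/(1+2) = 1/3
#' @export
cohesiveness <- function(network, genes, penalty = 2) {
  stopifnot(length(genes) > 0)
  a <- .adjacency(network)
  v <- match(genes, a$names)
  if (anyNA(v))
    stop("input error: gene(s) not in network: ",
         paste(genes[is.na(v)], collapse = ", "))
  .setStats(a, v, penalty)$cohesiveness
}

# internal/boundary weight, density and cohesiveness of a vertex-index set
.setStats <- function(a, v, penalty) {
  inV <- logical(a$n); inV[v] <- TRUE
  w_in <- 0; w_bound <- 0; n_edges <- 0L
  for (i in v) {
    nb <- a$adj[[i]]; wb <- a$adjw[[i]]
    int <- inV[nb]
    w_in <- w_in + sum(wb[int])       # counts each internal edge twice
    w_bound <- w_bound + sum(wb[!int])
    n_edges <- n_edges + sum(int)
  }
  w_in <- w_in / 2; n_edges <- n_edges %/% 2L
  k <- length(v)
  denom <- w_in + w_bound + penalty * k
  list(size = k, n_internal_edges = n_edges, internal_weight = w_in,
       boundary_weight = w_bound,
       cohesiveness = if (denom > 0) w_in / denom else 0,
       density = if (k >= 2L) n_edges / (k * (k - 1) / 2) else 0)
}

# connectivity of the induced subgraph on vertex indices v (BFS)
.isConnectedSet <- function(a, v) {
  if (length(v) <= 1L) return(TRUE)
  inV <- logical(a$n); inV[v] <- TRUE
  seen <- logical(a$n)
  queue <- v[1L]; seen[queue] <- TRUE
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    nb <- a$adj[[i]]
    nxt <- nb[inV[nb] & !seen[nb]]
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  all(seen[v])
}

# greedy cohesiveness growth from one seed vertex (indices, not names).
# Each step evaluates every boundary-node addition and every member removal,
# applies the single move with the largest strictly-improving cohesiveness
# (ties: smallest gene id; removals that disconnect the set are skipped),
# and stops at a local optimum.
.growCluster <- function(a, seed, penalty, eps = 1e-12) {
  inV <- logical(a$n)
  wtv <- numeric(a$n)                 # weight from each vertex into V
  members <- seed
  inV[seed] <- TRUE
  nb <- a$adj[[seed]]
  wtv[nb] <- wtv[nb] + a$adjw[[seed]]
  w_in <- 0
  w_bound <- a$strength[seed]
  f <- if (w_bound + penalty > 0) 0 else 0
  repeat {
    k <- length(members)
    cand_v <- integer(); cand_f <- numeric(); cand_type <- character()
    bd <- which(wtv > 0 & !inV)
    if (length(bd)) {
      wa <- wtv[bd]
      f_add <- (w_in + wa) /
        (w_in + wa + w_bound - wa + (a$strength[bd] - wa) + penalty * (k + 1))
      cand_v <- c(cand_v, bd)
      cand_f <- c(cand_f, f_add)
      cand_type <- c(cand_type, rep("add", length(bd)))
    }
    if (k > 1L) {
      wr <- wtv[members]
      num <- w_in - wr
      den <- num + w_bound + wr - (a$strength[members] - wr) +
        penalty * (k - 1)
      f_rem <- ifelse(den > 0, num / den, 0)
      cand_v <- c(cand_v, members)
      cand_f <- c(cand_f, f_rem)
      cand_type <- c(cand_type, rep("remove", k))
    }
    improving <- which(cand_f > f + eps)
    if (!length(improving)) break
    # best f first; ties broken by smallest gene id (radix, locale-free)
    o <- improving[order(-cand_f[improving],
                         .radixRank(a$names[cand_v[improving]]))]
    moved <- FALSE
    for (ci in o) {
      v <- cand_v[ci]
      if (cand_type[ci] == "add") {
        inV[v] <- TRUE
        members <- c(members, v)
        w_in <- w_in + wtv[v]
        w_bound <- w_bound - wtv[v] + (a$strength[v] - wtv[v])
        nb <- a$adj[[v]]
        wtv[nb] <- wtv[nb] + a$adjw[[v]]
        f <- cand_f[ci]; moved <- TRUE
        break
      } else {
        rest <- members[members != v]
        if (!.isConnectedSet(a, rest)) next
        inV[v] <- FALSE
        members <- rest
        w_in <- w_in - wtv[v]
        w_bound <- w_bound + wtv[v] - (a$strength[v] - wtv[v])
        nb <- a$adj[[v]]
        wtv[nb] <- wtv[nb] - a$adjw[[v]]
        f <- cand_f[ci]; moved <- TRUE
        break
      }
    }
    if (!moved) break
  }
  sort(members)
}

# rank of strings under radix (byte) order
.radixRank <- function(x) match(x, sort(unique(x), method = "radix"))

#' Grow a single module from a seed gene
#'
#' Runs the greedy cohesiveness growth from one seed and returns the gene
#' set of the resulting local optimum (always connected).
#'
#' @param network a [CoexpressionNetwork-class].
#' @param seed a gene id present in the network.
#' @param params a [detectionParams()] list (only \code{penalty} is used).
#' @return character vector of gene ids.
#' @export
growCluster <- function(network, seed, params = detectionParams()) {
  a <- .adjacency(network)
  s <- match(seed, a$names)
  if (is.na(s)) stop("input error: seed gene not in network: ", seed)
  sort(a$names[.growCluster(a, s, params$penalty)])
}

.moduleSet <- function(clusters, a, params) {
  k <- length(clusters)
  ids <- if (k) paste0("M", seq_len(k)) else character()
  stats <- do.call(rbind, lapply(clusters, function(v) {
    s <- .setStats(a, v, params$penalty)
    data.frame(size = s$size, n_internal_edges = s$n_internal_edges,
               internal_weight = s$internal_weight,
               boundary_weight = s$boundary_weight,
               cohesiveness = s$cohesiveness, density = s$density)
  }))
  if (is.null(stats))
    stats <- data.frame(size = integer(), n_internal_edges = integer(),
                        internal_weight = numeric(),
                        boundary_weight = numeric(),
                        cohesiveness = numeric(), density = numeric())
  stats <- cbind(data.frame(module_id = ids, stringsAsFactors = FALSE), stats)
  genes <- lapply(clusters, function(v) sort(a$names[v], method = "radix"))
  names(genes) <- ids
  new("ModuleSet", modules = genes, stats = stats,
      params = unclass(params))
}

#' Detect cohesive modules in a coexpression network
#'
#' Greedy cohesiveness-based clustering: seeds are processed in
#' degree-descending order (ties by gene id) over nodes not yet covered by a
#' kept module; each seed is grown with [growCluster()]; grown clusters
#' smaller than \code{minSize} or sparser than \code{minDensity} are
#' discarded; finally clusters whose match coefficient
#' \eqn{\omega(A,B) = |A \cap B|^2/(|A||B|)} reaches
#' \code{mergeOverlapOmega} are unioned transitively.  Fully deterministic
#' given the network and parameters.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param params a [detectionParams()] list.
#' @return a [ModuleSet-class].
#' @seealso [mergeModulesByOverlap()] for the post-hoc one-third overlap merge.
#' @export
detectModules <- function(network, params = detectionParams()) {
  a <- .adjacency(network)
  if (a$n == 0L) return(.moduleSet(list(), a, params))
  seeds <- order(-a$degree, .radixRank(a$names))
  covered <- logical(a$n)
  clusters <- list()
  for (s in seeds) {
    if (covered[s] || a$degree[s] == 0L) next
    v <- .growCluster(a, s, params$penalty)
    st <- .setStats(a, v, params$penalty)
    if (st$size >= params$minSize && st$density >= params$minDensity) {
      clusters[[length(clusters) + 1L]] <- v
      covered[v] <- TRUE
    }
  }
  clusters <- .omegaMerge(clusters, params$mergeOverlapOmega)
  .moduleSet(clusters, a, params)
}

# match coefficient omega(A, B) = |A n B|^2 / (|A| |B|)
.matchCoefficient <- function(A, B) {
  ov <- length(intersect(A, B))
  ov * ov / (length(A) * length(B))
}

# transitively union clusters with omega >= threshold (union-find)
.omegaMerge <- function(clusters, omega) {
  k <- length(clusters)
  if (k < 2L) return(clusters)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (.matchCoefficient(clusters[[i]], clusters[[j]]) >= omega) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(k), find, 0L)
  lapply(unique(roots), function(r)
    sort(unique(unlist(clusters[roots == r]))))
}

#' Merge modules by the one-third overlap rule
#'
#' Post-hoc merge applied after detection: two modules are merged when
#' strictly more than one third of the genes of the smaller module occur in
#' the larger one.  The rule is iterated to a fixed point; at each step the
#' pair with the largest overlap fraction is merged (ties: larger combined
#' size first, then lexicographically smallest member id), the union's
#' statistics are recomputed on the network, and the search restarts.  In the
#' output every pairwise overlap is at most one third of the smaller module.
#' Merged modules are not re-grown.
#'
#' @param modules a [ModuleSet-class].
#' @param network the [CoexpressionNetwork-class] the modules live in (used
#'   to recompute cohesiveness of merged unions).
#' @return a [ModuleSet-class] (module ids reassigned \code{M1..Mk}).
#' @export
mergeModulesByOverlap <- function(modules, network) {
  a <- .adjacency(network)
  sets <- lapply(moduleGenes(modules), function(g) {
    v <- match(g, a$names)
    if (anyNA(v))
      stop("input error: module gene(s) not in network: ",
           paste(g[is.na(v)], collapse = ", "))
    v
  })
  params <- modules@params
  if (is.null(params$penalty)) params <- unclass(detectionParams())
  repeat {
    k <- length(sets)
    if (k < 2L) break
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      ov <- length(intersect(sets[[i]], sets[[j]]))
      smin <- min(length(sets[[i]]), length(sets[[j]]))
      if (3L * ov > smin) {   # strictly more than one third, exact arithmetic
        cand <- list(i = i, j = j, frac = ov / smin,
                     comb = length(sets[[i]]) + length(sets[[j]]),
                     lex = sort(a$names[union(sets[[i]], sets[[j]])],
                                method = "radix")[1L])
        if (is.null(best) ||
            cand$frac > best$frac + 1e-15 ||
            (abs(cand$frac - best$frac) <= 1e-15 &&
             (cand$comb > best$comb ||
              (cand$comb == best$comb && cand$lex < best$lex))))
          best <- cand
      }
    }
    if (is.null(best)) break
    merged <- sort(union(sets[[best$i]], sets[[best$j]]))
    sets <- c(sets[-c(best$i, best$j)], list(merged))
  }
  # deterministic output order: by size descending, then first gene id
  if (length(sets)) {
    first <- vapply(sets, function(v) sort(a$names[v], method = "radix")[1L],
                    "")
    sets <- sets[order(-lengths(sets), .radixRank(first))]
  }
  .moduleSet(sets, a, params)
}
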