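#' Poincare-disk distance
#'
#' Metric of the hyperbolic plane in the Poincare disk model:
#' `d = arccosh(1 + 2|a-b|^2 / ((1-|a|^2)(1-|b|^2)))`.
#'
#' @param a,b Complex scalars/vectors (or length-2 numerics) strictly inside
#'   the unit disk.
#' @return Nonnegative distance(s); symmetric; zero iff `a == b`.
#' @export
hyperbolic_distance <- function(a, b) {
  if (!is.complex(a)) a <- complex(real = a[1], imaginary = a[2])
  if (!is.complex(b)) b <- complex(real = b[1], imaginary = b[2])
  if (any(Mod(a) >= 1) || any(Mod(b) >= 1))
    stop("coordinates must lie strictly inside the unit disk")
  acosh(1 + 2 * Mod(a - b)^2 / ((1 - Mod(a)^2) * (1 - Mod(b)^2)))
}

mobius <- function(z, u) (u + z) / (1 + Conj(z) * u)

#' Build a hyperbolic SOM lattice
#'
#' Constructs the node lattice of a hierarchically grown hyperbolic SOM: the
#' vertices of the regular `{3, branching}` triangular tessellation of the
#' hyperbolic plane out to `rings` rings around a centre node, realised in the
#' Poincare disk. Ring sizes follow `V_1 = branching`,
#' `V_{r+1} = (branching - 4) V_r - V_{r-1}`; for the default eight-neighbour
#' topology with three rings this gives 1 + 8 + 32 + 120 = 161 nodes.
#'
#' @param rings Number of rings (>= 1).
#' @param branching Vertex degree of the tessellation; must be >= 7 (at 6 the
#'   tessellation degenerates to the Euclidean plane).
#' @return An `h2som_lattice`: list with complex `coords`, integer `ring`,
#'   `ring_ids` (node ids per ring, centre = ring 0), `parents` and
#'   `children` (lists of integer ids), `neighbors` (symmetric adjacency
#'   list), and the tessellation `edge_length`.
#' @export
build_lattice <- function(rings = 3L, branching = 8L) {
  rings <- as.integer(rings); b <- as.integer(branching)
  if (rings < 1L) stop("rings must be >= 1")
  if (b <= 6L) stop("branching must be >= 7 for a hyperbolic tessellation")
  ca <- cos(2 * pi / b)
  l <- acosh(ca / (1 - ca))
  te <- tanh(l / 2)

  coords <- complex(real = 0, imaginary = 0)
  ring <- 0L
  parents <- list(integer(0))
  neighbors <- list(integer(0))
  add_edge <- function(i, j) {
    neighbors[[i]] <<- union(neighbors[[i]], j)
    neighbors[[j]] <<- union(neighbors[[j]], i)
  }

  # ring 1
  ids1 <- seq_len(b) + 1L
  coords <- c(coords, te * exp(2i * pi * (seq_len(b) - 1) / b))
  ring <- c(ring, rep(1L, b))
  for (i in ids1) { parents[[i]] <- 1L; neighbors[[i]] <- integer(0) }
  for (i in ids1) add_edge(1L, i)
  for (k in seq_len(b)) add_edge(ids1[k], ids1[1L + (k %% b)])
  ring_ids <- list(`0` = 1L, `1` = ids1)

  for (r in seq_len(rings - 1L)) {
    cur <- ring_ids[[r + 1L]]
    gen <- list()   # candidate children: list of (parent id, coordinate)
    for (v in cur) {
      z <- coords[v]
      known <- c(parents[[v]], intersect(neighbors[[v]], cur))
      angs <- vapply(known, function(wid) {
        Arg((coords[wid] - z) / (1 - Conj(z) * coords[wid]))
      }, numeric(1))
      base <- angs[1]
      slots <- as.integer(round(((angs - base) %% (2 * pi)) / (2 * pi / b))) %% b
      free <- setdiff(0:(b - 1L), slots)
      for (s in free) {
        u <- te * exp(1i * (base + s * 2 * pi / b))
        gen[[length(gen) + 1L]] <- list(parent = v, z = mobius(z, u))
      }
    }
    zs <- vapply(gen, function(g) g$z, complex(1))
    ps <- vapply(gen, function(g) g$parent, integer(1))
    # dedupe shared children (generated once per adjacent parent)
    ord <- order(Arg(zs) %% (2 * pi))
    zs <- zs[ord]; ps <- ps[ord]
    grp <- cumsum(c(TRUE, Mod(diff(zs)) > 1e-4))
    if (Mod(zs[1] - zs[length(zs)]) <= 1e-4) grp[grp == max(grp)] <- 1L
    uniq <- sort(unique(grp))
    new_ids <- length(coords) + seq_along(uniq)
    for (k in seq_along(uniq)) {
      sel <- grp == uniq[k]
      id <- new_ids[k]
      coords <- c(coords, zs[which(sel)[1]])
      ring <- c(ring, r + 1L)
      parents[[id]] <- sort(unique(ps[sel]))
      neighbors[[id]] <- integer(0)
      for (p in parents[[id]]) add_edge(p, id)
    }
    nn <- length(new_ids)
    for (k in seq_len(nn)) add_edge(new_ids[k], new_ids[1L + (k %% nn)])
    ring_ids[[r + 2L]] <- new_ids
    names(ring_ids)[r + 2L] <- as.character(r + 1L)
  }

  children <- lapply(seq_along(coords), function(i) integer(0))
  for (i in seq_along(coords)) {
    for (p in parents[[i]]) children[[p]] <- c(children[[p]], i)
  }

  lat <- structure(list(coords = coords, ring = ring, ring_ids = ring_ids,
                        parents = parents, children = children,
                        neighbors = neighbors, edge_length = l,
                        rings = rings, branching = b),
                   class = "h2som_lattice")
  # internal consistency with the tessellation recurrence
  v <- c(b, (b - 4) * b)
  sizes <- lengths(ring_ids)[-1]
  expect <- c(b, if (rings > 1) {
    vv <- b; prev <- 0
    out <- integer(0)
    for (r in 2:rings) { nxt <- (b - 4) * vv - prev; out <- c(out, nxt)
      prev <- vv; vv <- nxt }
    out
  })
  if (!all(sizes == expect[seq_len(rings)]))
    stop("lattice construction produced inconsistent ring sizes")
  lat
}

#' @export
print.h2som_lattice <- function(x, ...) {
  cat(sprintf("<h2som_lattice: {3,%d} tessellation, %d ring(s), %d nodes (%s)>\n",
              x$branching, x$rings, length(x$coords),
              paste(lengths(x$ring_ids), collapse = "+")))
  invisible(x)
}

# m x m matrix of pairwise hyperbolic node distances
lattice_distances <- function(lat) {
  z <- lat$coords
  m <- length(z)
  az <- Mod(z)^2
  d2 <- outer(z, z, function(a, b) Mod(a - b)^2)
  acosh(1 + 2 * d2 / outer(1 - az, 1 - az))
}

#' Fit a hierarchically grown hyperbolic SOM
#'
#' Vector quantization of the feature space on a hyperbolic lattice. Training
#' proceeds ring by ring: ring 1 receives standard SOM updates
#' (`u <- u + alpha * h(d_hyp) * (x - u)` with a Gaussian neighbourhood kernel
#' in the hyperbolic node distances); each subsequent ring is initialized from
#' its parent prototypes plus a small seeded jitter and trained on winners
#' found by beam descent through the already-trained rings. The learning rate
#' decays exponentially between `alpha[1]` and `alpha[2]` within each phase;
#' the kernel width decays from the ring's inter-node spacing to a quarter of
#' it. The total number of update steps is `iter_mult * nrow(x)`, split evenly
#' across phases.
#'
#' @param x Numeric matrix of feature vectors (rows), e.g. median RGB.
#' @param rings,branching Lattice parameters (see [build_lattice()]).
#' @param iter_mult Update steps per training vector (default 30).
#' @param alpha Learning-rate start and end.
#' @param seed RNG seed; training is deterministic per seed.
#' @return An object of class `h2som`: the lattice, the `n_nodes x 3`
#'   prototype matrix, the training schedule, and the precomputed node
#'   distance matrix.
#' @export
h2som <- function(x, rings = 3L, branching = 8L, iter_mult = 30,
                  alpha = c(0.99, 0.1), seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty training data")
  if (!all(is.finite(x))) stop("training features must be finite")
  lat <- build_lattice(rings, branching)
  D <- lattice_distances(lat)
  m <- length(lat$coords)
  set.seed(seed)
  mu <- colMeans(x)
  rng <- apply(x, 2, range)
  P <- matrix(rep(mu, each = m), m)
  jit <- function(n, sd) matrix(stats::rnorm(n * ncol(x), 0, sd), n)
  clamp_bbox <- function(M) {
    for (c in seq_len(ncol(M)))
      M[, c] <- pmin(pmax(M[, c], rng[1, c]), rng[2, c])
    M
  }
  steps <- ceiling(iter_mult * nrow(x) / rings)
  l <- lat$edge_length
  for (r in seq_len(rings)) {
    ids <- lat$ring_ids[[r + 1L]]
    if (r == 1L) {
      P[ids, ] <- clamp_bbox(P[ids, , drop = FALSE] + jit(length(ids), 2))
    } else {
      for (id in ids) {
        p <- lat$parents[[id]][1]
        P[id, ] <- P[p, ]
      }
      P[ids, ] <- clamp_bbox(P[ids, , drop = FALSE] + jit(length(ids), 2))
    }
    ord <- sample.int(nrow(x), steps, replace = TRUE)
    P <- .h2som_phase_cpp(x, P, D, lat$ring_ids[[2L]], lat$children,
                          as.integer(r), ids, ord,
                          alpha[1], alpha[2], l, l / 4)
  }
  structure(list(lattice = lat, prototypes = P, trained = TRUE,
                 schedule = list(iter_mult = iter_mult, alpha = alpha,
                                 steps_per_phase = steps, seed = seed),
                 D = D, n = nrow(x)),
            class = "h2som")
}

#' @export
print.h2som <- function(x, ...) {
  cat(sprintf("<h2som: %d prototypes (%d rings, branching %d), trained on %d vectors>\n",
              nrow(x$prototypes), x$lattice$rings, x$lattice$branching, x$n))
  invisible(x)
}

#' Best matching unit(s)
#'
#' `search = "exhaustive"` scans all prototypes (ties to the lowest node id);
#' `search = "beam"` descends the hierarchy ring by ring, following the best
#' child of the current node -- cheaper on large lattices, and usually but not
#' always identical to the exhaustive result.
#'
#' @param model A fitted [h2som()].
#' @param x Numeric matrix of feature vectors (rows), or a single vector.
#' @param search `"exhaustive"` or `"beam"`.
#' @return Integer node ids (1-based).
#' @export
bmu <- function(model, x, search = c("exhaustive", "beam")) {
  search <- match.arg(search)
  if (!isTRUE(model$trained)) stop("model is not trained")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (search == "exhaustive")
    return(as.integer(.bmu_cpp(model$prototypes, x)))
  lat <- model$lattice
  P <- model$prototypes
  vapply(seq_len(nrow(x)), function(i) {
    xi <- x[i, ]
    pool <- lat$ring_ids[[2L]]
    cur <- pool[which.min(colSums((t(P[pool, , drop = FALSE]) - xi)^2))]
    best <- cur
    repeat {
      kids <- lat$children[[cur]]
      if (length(kids) == 0L) break
      cur <- kids[which.min(colSums((t(P[kids, , drop = FALSE]) - xi)^2))]
      if (sum((P[cur, ] - xi)^2) < sum((P[best, ] - xi)^2)) best <- cur
    }
    # also consider the centre node for completeness
    if (sum((P[1L, ] - xi)^2) < sum((P[best, ] - xi)^2)) best <- 1L
    best
  }, integer(1))
}

#' @export
predict.h2som <- function(object, newdata, search = "exhaustive", ...) {
  bmu(object, newdata, search = search)
}

#' Mean quantization error
#'
#' Mean Euclidean distance between feature vectors and their best matching
#' prototypes.
#'
#' @param model A fitted [h2som()].
#' @param x Feature matrix.
#' @return Nonnegative scalar.
#' @export
quantization_error <- function(model, x) {
  x <- as.matrix(x)
  ids <- bmu(model, x)
  mean(sqrt(rowSums((x - model$prototypes[ids, , drop = FALSE])^2)))
}

#' Serialize an H2SOM model to JSON
#'
#' @param model A fitted [h2som()].
#' @param path Output JSON path.
#' @return `read_h2som()` returns the model.
#' @export
write_h2som <- function(model, path) {
  lat <- model$lattice
  obj <- list(rings = lat$rings, branching = lat$branching,
              schedule = model$schedule, n = model$n,
              prototypes = unname(as.matrix(model$prototypes)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_h2som
#' @export
read_h2som <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lat <- build_lattice(obj$rings, obj$branching)
  structure(list(lattice = lat, prototypes = as.matrix(obj$prototypes),
                 trained = TRUE, schedule = obj$schedule,
                 D = lattice_distances(lat), n = obj$n),
            class = "h2som")
}
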