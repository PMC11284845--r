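# Independent oracles and toy-structure builders. Oracles deliberately
# avoid the code paths they check: permutations are enumerated directly,
# rotations are searched numerically.

RT298 <- confsel_constants$R * 298.15

# all permutations of 1..n (n small), deterministic order
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# plain RMSD after centroid shift + rotation found by numerical search
# (multi-start Nelder-Mead over Euler angles) -- oracle for kabsch_rmsd
rotation_search_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  euler <- function(a) {
    Rz <- matrix(c(cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1]), 0,
                   0, 0, 1), 3)
    Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0,
                   sin(a[2]), 0, cos(a[2])), 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(a[3]), sin(a[3]),
                   0, -sin(a[3]), cos(a[3])), 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(a) sqrt(mean(rowSums((P %*% t(euler(a)) - Q)^2)))
  best <- Inf
  set.seed(11)
  for (i in 1:40) {
    fit <- stats::optim(stats::runif(3, -pi, pi), obj,
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# minimum kabsch_rmsd over ALL element-preserving heavy-atom permutations
# (ignores bond graphs entirely) -- oracle for symmetry_rmsd on small toys
brute_perm_rmsd <- function(A, B) {
  h <- heavy_atoms(A)
  best <- Inf
  for (p in all_perms(length(h))) {
    map <- h[unlist(p)]
    if (!identical(A$elements[h], B$elements[map])) next
    attr(map, "heavy_a") <- h
    best <- min(best, kabsch_rmsd(A, B, map))
  }
  best
}

# count of element- and adjacency-preserving permutations of a
# molecular_graph (heavy atoms only) -- oracle for enumerate_isomorphisms
brute_automorphism_count <- function(g) {
  h <- confsel:::heavy_subgraph(g)$graph
  n <- length(h$elements)
  adj <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(h$edges)))
    adj[h$edges[r, 1], h$edges[r, 2]] <- adj[h$edges[r, 2], h$edges[r, 1]] <- TRUE
  count <- 0L
  for (p in all_perms(n)) {
    p <- unlist(p)
    if (!identical(h$elements, h$elements[p])) next
    if (identical(adj, adj[p, p])) count <- count + 1L
  }
  count
}

rigid_transform <- function(s, angles = c(0.3, -1.1, 0.7),
                            shift = c(1, -2, 3)) {
  Rz <- matrix(c(cos(angles[1]), sin(angles[1]), 0,
                 -sin(angles[1]), cos(angles[1]), 0, 0, 0, 1), 3)
  Ry <- matrix(c(cos(angles[2]), 0, -sin(angles[2]), 0, 1, 0,
                 sin(angles[2]), 0, cos(angles[2])), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(angles[3]), sin(angles[3]),
                 0, -sin(angles[3]), cos(angles[3])), 3)
  s$coords <- s$coords %*% t(Rz %*% Ry %*% Rx) +
    matrix(shift, nrow(s$coords), 3, byrow = TRUE)
  s
}

# --- toy structures ------------------------------------------------------

toy_water <- function() {
  conformer(c("O", "H", "H"),
            rbind(c(0, 0, 0), c(0.9572, 0, 0), c(-0.24, 0.9266, 0)))
}

toy_methane <- function() {
  a <- 1.09 / sqrt(3)
  conformer(c("C", "H", "H", "H", "H"),
            rbind(c(0, 0, 0), c(a, a, a), c(a, -a, -a), c(-a, a, -a),
                  c(-a, -a, a)))
}

# heavy-atom-only skeletons (no hydrogens) for graph/torsion cases
toy_ring <- function(n, element = "C", r = 1.4) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  conformer(rep(element, n), cbind(r * cos(th), r * sin(th), 0))
}

toy_chain <- function(elements, bond = 1.52) {
  n <- length(elements)
  # zigzag in the xy plane so dihedrals are defined
  x <- (seq_len(n) - 1) * bond * cos(pi / 6)
  y <- rep(c(0, bond * sin(pi / 6)), length.out = n)
  conformer(elements, cbind(x, y, 0))
}

ring_graph <- function(n, element = "C") {
  molecular_graph(rep(element, n), cbind(seq_len(n), c(seq_len(n)[-1], 1)))
}

path_graph <- function(elements) {
  n <- length(elements)
  molecular_graph(elements, cbind(seq_len(n - 1), seq_len(n - 1) + 1))
}

# write a conformer ensemble to a temp xyz file, return the path
write_temp_xyz <- function(text) {
  path <- tempfile(fileext = ".xyz")
  writeLines(text, path)
  path
}
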