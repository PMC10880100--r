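#' Exact muscle-tendon lengths from via-point geometry
#'
#' Computes muscle-tendon unit path lengths by forward kinematics of the
#' via points (straight-line segments between points fixed in segment
#' frames). This is the reference geometry from which the polynomial
#' parameterisation is fitted, and serves as the exact oracle in tests.
#'
#' @param model a [hop_model()].
#' @param q matrix (n x n_coordinates) of coordinate values (rad / m), or a
#'   named vector for a single pose.
#' @return Matrix (n x n_mtus) of path lengths (m).
#' @export
mtu_length_reference <- function(model, q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  nt <- nrow(q)
  zero <- matrix(0, nt, ncol(q))
  fk <- cpp_forward_kinematics(model_blob_bare(model), q, zero, zero)
  sapply(names(model$paths), function(mn) {
    p <- model$paths[[mn]]
    si <- match(p$segment, model$segments$name)
    ct <- cos(fk$theta[, si, drop = FALSE]); st <- sin(fk$theta[, si, drop = FALSE])
    wx <- fk$ox[, si, drop = FALSE] +
      sweep(ct, 2, p$x, `*`) - sweep(st, 2, p$y, `*`)
    wy <- fk$oy[, si, drop = FALSE] +
      sweep(st, 2, p$x, `*`) + sweep(ct, 2, p$y, `*`)
    L <- 0
    for (k in seq_len(nrow(p) - 1)) {
      L <- L + sqrt((wx[, k + 1] - wx[, k])^2 + (wy[, k + 1] - wy[, k])^2)
    }
    L
  })
}

# blob that works before polynomials are fitted
model_blob_bare <- function(model) {
  m <- model
  m$polynomials <- NULL
  model_blob(m)
}

#' Reference moment arms by central differences of the exact length
#' @param model a [hop_model()].
#' @param q pose matrix (n x n_coordinates).
#' @param coords coordinate names to differentiate against.
#' @param h finite-difference step (rad).
#' @return list of matrices (n x length(coords)), one per muscle.
#' @export
mtu_moment_arm_reference <- function(model, q, coords, h = 1e-6) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  idx <- match(coords, model$coordinates)
  nm <- length(model$paths)
  arms <- replicate(nm, matrix(0, nrow(q), length(idx)), simplify = FALSE)
  names(arms) <- names(model$paths)
  for (k in seq_along(idx)) {
    qp <- q; qp[, idx[k]] <- qp[, idx[k]] + h
    qm <- q; qm[, idx[k]] <- qm[, idx[k]] - h
    dL <- (mtu_length_reference(model, qp) - mtu_length_reference(model, qm)) / (2 * h)
    for (j in seq_len(nm)) arms[[j]][, k] <- -dL[, j]
  }
  arms
}

#' Sample random training poses for the polynomial fit
#'
#' Uniform deterministic sampling of the coordinate hypercube used to fit the
#' muscle-geometry polynomials. Ranges should extend beyond the expected
#' range of motion.
#'
#' @param ranges named list of length-2 numeric ranges (rad), one per
#'   rotational coordinate to sample.
#' @param n number of poses.
#' @param seed integer seed (sampling is deterministic given the seed).
#' @param min_n minimal admissible `n` (e.g. the number of polynomial
#'   coefficients to identify).
#' @return A tibble with one column per coordinate in `ranges`.
#' @export
sample_training_poses <- function(ranges, n = 2000, seed = 1, min_n = NULL) {
  if (!is.null(min_n) && n < min_n) {
    stop(sprintf("n = %d poses is too small: at least %d required", n, min_n))
  }
  state <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(state)) assign(".Random.seed", state, envir = globalenv()))
  set.seed(seed)
  out <- lapply(ranges, function(r) runif(n, r[1], r[2]))
  tibble::as_tibble(out)
}

monomial_exponents <- function(nvar, degree) {
  grid <- do.call(expand.grid, rep(list(0:degree), nvar))
  grid <- as.matrix(grid[rowSums(grid) <= degree, , drop = FALSE])
  storage.mode(grid) <- "integer"
  grid[order(rowSums(grid)), , drop = FALSE]
}

monomial_basis <- function(q, expo) {
  out <- matrix(1, nrow(q), nrow(expo))
  for (k in seq_len(ncol(expo))) {
    e <- expo[, k]
    pos <- which(e > 0)
    if (length(pos)) out[, pos] <- out[, pos] * outer(q[, k], e[pos], `^`)
  }
  out
}

#' Fit polynomial muscle geometry
#'
#' Fits, for every MTU, a multivariate polynomial of the spanned joint angles
#' to the exact via-point path length, by ordinary least squares on randomly
#' sampled poses. Moment arms are obtained analytically as the negative
#' partial derivatives of the fitted length polynomial, which makes the
#' moment-arm/length-derivative identity exact by construction.
#'
#' @param model a [hop_model()].
#' @param degree total polynomial degree.
#' @param n number of training poses.
#' @param seed sampling seed.
#' @param margin fractional widening of the expected range of motion.
#' @param tol maximum admissible length residual (m) before an error is
#'   raised.
#' @return The model with a `polynomials` field: per muscle a list with
#'   `coords` (coordinate indices), `expo`, `coef`, `degree`, `fit_domain`
#'   and `fit_error` (max |length residual| on the training poses).
#' @export
fit_mtu_polynomials <- function(model, degree = 4, n = 2000, seed = 1,
                                margin = 0.2, tol = 8e-3) {
  rot <- names(model$rom)
  ranges <- lapply(model$rom, function(r) r + c(-1, 1) * margin * diff(r))
  nexp_max <- nrow(monomial_exponents(2, degree))
  poses <- sample_training_poses(ranges, n = n, seed = seed, min_n = 2 * nexp_max)
  Q <- matrix(0, n, length(model$coordinates),
              dimnames = list(NULL, model$coordinates))
  for (cn in rot) Q[, cn] <- poses[[cn]]
  L <- mtu_length_reference(model, Q)
  # spanned coordinates: those whose variation moves the muscle's segments
  spans <- muscle_spanned_coords(model)
  polys <- lapply(seq_along(model$paths), function(j) {
    cn <- spans[[j]]
    ci <- match(cn, model$coordinates)
    expo <- monomial_exponents(length(ci), degree)
    X <- monomial_basis(Q[, ci, drop = FALSE], expo)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      stop(sprintf("ill-conditioned polynomial fit for %s: reduce the degree",
                   names(model$paths)[j]))
    }
    cf <- qr.coef(qrX, L[, j])
    resid <- L[, j] - X %*% cf
    ferr <- max(abs(resid))
    if (ferr > tol) {
      stop(sprintf("polynomial fit error %.2e m for %s exceeds tolerance %.1e",
                   ferr, names(model$paths)[j], tol))
    }
    list(mtu_name = names(model$paths)[j],
         coords = ci, coord_names = cn, expo = expo, coef = as.numeric(cf),
         degree = degree,
         fit_domain = ranges[cn],
         fit_error = ferr)
  })
  names(polys) <- names(model$paths)
  model$polynomials <- polys
  model
}

# coordinates spanned by each muscle: joints strictly between the path's
# outermost segments along the kinematic chain
muscle_spanned_coords <- function(model) {
  seg <- model$segments
  chain <- function(name) {
    out <- character(0)
    while (!is.na(name)) {
      out <- c(name, out)
      name <- seg$parent[match(name, seg$name)]
    }
    out
  }
  lapply(model$paths, function(p) {
    segs <- unique(p$segment)
    chains <- lapply(segs, chain)
    longest <- chains[[which.max(lengths(chains))]]
    # joints crossed between first (most proximal) attachment and the deepest one
    top <- segs[which.min(vapply(chains, length, 1L))]
    crossed <- longest[(match(top, longest) + 1):length(longest)]
    joints <- seg$parent_joint[match(crossed, seg$name)]
    intersect(model$coordinates, joints)
  })
}

#' Evaluate the polynomial muscle geometry
#'
#' @param model a [hop_model()] with fitted polynomials.
#' @param q,qd coordinate positions and velocities (n x n_coordinates).
#' @param warn_domain warn when a pose leaves the polynomial fit domain.
#' @return A list with `length` (n x n_mtus), `velocity` (lengthening rate,
#'   m/s, equal to the chain-rule contraction `sum_k dL/dq_k * qd_k`) and
#'   `moment_arms` (list per muscle of n x n_spanned matrices,
#'   `r_k = -dL/dq_k`).
#' @export
eval_mtu <- function(model, q, qd = NULL, warn_domain = TRUE) {
  stopifnot(!is.null(model$polynomials))
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  if (is.null(qd)) qd <- matrix(0, nrow(q), ncol(q))
  if (is.null(dim(qd))) qd <- matrix(qd, nrow = 1)
  if (warn_domain) {
    for (p in model$polynomials) {
      for (k in seq_along(p$coords)) {
        r <- p$fit_domain[[k]]
        x <- q[, p$coords[k]]
        if (any(x < r[1] - 1e-9 | x > r[2] + 1e-9)) {
          warning(sprintf("pose outside polynomial fit domain for %s (%s)",
                          p$mtu_name, p$coord_names[k]))
          break
        }
      }
    }
  }
  out <- cpp_eval_mtu(model_blob(model), q, qd)
  names(out$moment_arms) <- names(model$paths)
  colnames(out$length) <- names(model$paths)
  colnames(out$velocity) <- names(model$paths)
  out
}
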