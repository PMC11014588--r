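# Fast forward engine for the spectral DCM likelihood.
#
# The predicted CSD factorizes through the eigendecomposition A = V L V^-1:
#   (iwI - A)^-1 = V diag(1/(iw - l)) V^-1
#   S(w) = w^-bv * V ( Mtil o d(w) d(w)^H ) V^H,
#     Mtil = V^-1 diag(exp(av)) V^-H,  d(w) = 1/(iw - l)
# so the frequency loop reduces to Hadamard products and two small
# complex matrix products, and the finite-difference Jacobian can reuse
# every stage a perturbed coordinate does not touch (perturbing a noise
# amplitude does not re-eigendecompose A; perturbing one region's
# hemodynamics only redoes the sandwich).  A per-frequency linear-solve
# fallback covers (near-)defective A.

# residue form of the hemodynamic transfer for one region: H over all
# omegas via eigendecomposition of the 4x4 linearized system
hemo_transfer_col <- function(decay, transit, omega) {
  ss <- hemo_state_space(decay, transit)
  e <- eigen(ss$A)
  w <- solve(e$vectors, ss$B)
  cv <- as.vector(ss$C %*% e$vectors)
  # H(w) = sum_k cv_k w_k / (i w - l_k)
  out <- complex(length(omega))
  for (k in 1:4) out <- out + cv[k] * w[k] / (1i * omega - e$values[k])
  out
}

csd_engine <- function(layout, grid) {
  omega <- grid$omega
  nf <- length(omega)
  n <- layout$n
  idx_A <- layout$idx_A
  idx_hemo <- layout$idx_hemo
  idx_noise <- layout$idx_noise

  unpack <- function(theta) {
    A <- matrix(theta[idx_A], n, n)
    diag(A) <- -0.5 * exp(diag(A))
    h <- theta[idx_hemo]
    nn <- theta[idx_noise]
    list(A = A, decay = h[seq_len(n)], transit = h[n + seq_len(n)],
         v_amp = nn[seq_len(n)], v_exp = nn[n + 1],
         e_amp = nn[n + 1 + seq_len(n)], e_exp = nn[2 * n + 2])
  }

  # stage 1: eigen pieces of A (fallback flag when ill-conditioned)
  stage_A <- function(A) {
    e <- tryCatch(eigen(A), error = function(err) NULL)
    ok <- !is.null(e) && all(is.finite(e$values))
    if (ok) {
      Vi <- tryCatch(solve(e$vectors), error = function(err) NULL)
      ok <- !is.null(Vi) &&
        max(Mod(Vi)) * max(Mod(e$vectors)) < 1e12
    }
    if (!ok) return(list(fallback = TRUE, A = A))
    DD <- vector("list", nf)
    R <- vector("list", nf)
    for (k in seq_len(nf)) {
      d <- 1 / (1i * omega[k] - e$values)
      DD[[k]] <- outer(d, Conj(d))
      R[[k]] <- e$vectors %*% (d * Vi) # resolvent (iwI - A)^-1
    }
    list(fallback = FALSE, A = A, V = e$vectors, Vi = Vi, DD = DD,
         R = R)
  }

  # stage 2: neuronal cross spectra before the power-law profile
  stage_S <- function(sa, v_amp) {
    S <- vector("list", nf)
    if (sa$fallback) {
      I <- diag(n)
      gv <- exp(v_amp)
      for (k in seq_len(nf)) {
        M <- 1i * omega[k] * I - sa$A
        Mi <- solve(M, I)
        S[[k]] <- (Mi * rep(gv, each = n)) %*% Conj(t(Mi))
      }
    } else {
      Mtil <- sa$Vi %*% (exp(v_amp) * Conj(t(sa$Vi)))
      VH <- Conj(t(sa$V))
      for (k in seq_len(nf)) {
        S[[k]] <- sa$V %*% (Mtil * sa$DD[[k]]) %*% VH
      }
    }
    S
  }

  # stage 3: hemodynamic transfer matrix (nf x n)
  stage_H <- function(decay, transit) {
    H <- matrix(0i, nf, n)
    done <- list()
    for (r in seq_len(n)) {
      key <- paste(decay[r], transit[r])
      if (is.null(done[[key]])) done[[key]] <-
          hemo_transfer_col(decay[r], transit[r], omega)
      H[, r] <- done[[key]]
    }
    H
  }

  pl_exp <- function(le) if (identical(le, -Inf)) 0 else exp(le)

  # stage 4: sandwich + observation noise -> stacked feature vector
  assemble <- function(S, H, v_exp, e_amp, e_exp) {
    bv <- pl_exp(v_exp)
    be <- pl_exp(e_exp)
    profv <- omega^(-bv)
    profe <- omega^(-be)
    ge0 <- exp(e_amp)
    y <- numeric(2 * n * n * nf)
    blk <- 2 * n * n
    for (k in seq_len(nf)) {
      G <- (H[k, ] * S[[k]]) * rep(Conj(H[k, ]), each = n) * profv[k]
      diag(G) <- diag(G) + ge0 * profe[k]
      o <- (k - 1) * blk
      y[o + seq_len(n * n)] <- Re(G)
      y[o + n * n + seq_len(n * n)] <- Im(G)
    }
    y
  }

  predict_theta <- function(theta) {
    p <- unpack(theta)
    sa <- stage_A(p$A)
    S <- stage_S(sa, p$v_amp)
    H <- stage_H(p$decay, p$transit)
    assemble(S, H, p$v_exp, p$e_amp, p$e_exp)
  }

  # analytic derivatives of the stacked features with respect to the
  # whole connectivity block, via the resolvent identity
  #   d(iwI - A)^-1 / dA_ij = R E_ij R
  # so dG_ij = Hrow (R E_ij S0 + h.c.) Hcol.  With U = diag(H) R and
  # W = S0 diag(H*), the two terms over ALL (i,j) collapse into two
  # Kronecker products per frequency.
  perm_t <- as.vector(t(matrix(seq_len(n * n), n, n)))
  kx1 <- rep(seq_len(n), each = n) # Kronecker index expansion
  kx2 <- rep(seq_len(n), times = n)
  kron_small <- function(X, Y) {
    X[kx1, kx1, drop = FALSE] * Y[kx2, kx2, drop = FALSE]
  }
  a_block_jac <- function(sa, S, H, profv, diag_scale) {
    blk <- 2 * n * n
    JA <- matrix(0, blk * nf, n * n)
    for (k in seq_len(nf)) {
      S0 <- S[[k]] * profv[k]
      U <- H[k, ] * sa$R[[k]]
      W <- S0 * rep(Conj(H[k, ]), each = n)
      M <- kron_small(t(W), U) +
        kron_small(Conj(U), Conj(t(W)))[, perm_t, drop = FALSE]
      o <- (k - 1) * blk
      JA[o + seq_len(n * n), ] <- Re(M)
      JA[o + n * n + seq_len(n * n), ] <- Im(M)
    }
    # chain rule for the log-scaled diagonal entries
    JA * rep(diag_scale, each = blk * nf)
  }

  jacobian_theta <- function(theta, g0 = NULL, step = 1e-4) {
    p <- unpack(theta)
    sa <- stage_A(p$A)
    S <- stage_S(sa, p$v_amp)
    H <- stage_H(p$decay, p$transit)
    if (is.null(g0)) g0 <- assemble(S, H, p$v_exp, p$e_amp, p$e_exp)
    d <- layout$d
    J <- matrix(0, length(g0), d)
    profv <- omega^(-pl_exp(p$v_exp))
    blk <- 2 * n * n
    if (!sa$fallback) {
      diag_scale <- rep(1, n * n)
      dpos <- (seq_len(n) - 1) * n + seq_len(n)
      diag_scale[dpos] <- diag(p$A) # dA_ii/dtheta = A_ii (log scale)
      J[, idx_A] <- a_block_jac(sa, S, H, profv, diag_scale)
      # noise block: all derivatives are available in closed form
      bv <- pl_exp(p$v_exp)
      be <- pl_exp(p$e_exp)
      profe <- omega^(-be)
      lnw <- log(omega)
      ge0 <- exp(p$e_amp)
      diag_pos <- seq(1, n * n, by = n + 1)
      for (k in seq_len(nf)) {
        o <- (k - 1) * blk
        U <- H[k, ] * sa$R[[k]]
        # d/d v_amp[r]: rank-one neuronal term
        for (r in seq_len(n)) {
          dG <- exp(p$v_amp[r]) * profv[k] * outer(U[, r],
                                                   Conj(U[, r]))
          J[o + seq_len(n * n), idx_noise[r]] <- Re(dG)
          J[o + n * n + seq_len(n * n), idx_noise[r]] <- Im(dG)
        }
        # d/d v_exp: scales the whole neuronal part by -ln(w) * bv
        Gv_part <- (H[k, ] * (S[[k]] * profv[k])) *
          rep(Conj(H[k, ]), each = n)
        dG <- -lnw[k] * bv * Gv_part
        J[o + seq_len(n * n), idx_noise[n + 1]] <- Re(dG)
        J[o + n * n + seq_len(n * n), idx_noise[n + 1]] <- Im(dG)
        # d/d e_amp[r] and d/d e_exp: diagonal observation-noise terms
        for (r in seq_len(n)) {
          J[o + diag_pos[r], idx_noise[n + 1 + r]] <- ge0[r] * profe[k]
        }
        J[o + diag_pos, idx_noise[2 * n + 2]] <-
          -lnw[k] * be * ge0 * profe[k]
      }
    }
    for (i in seq_len(d)) {
      th <- theta
      th[i] <- th[i] + step
      q <- unpack(th)
      if (i %in% idx_A || i %in% idx_noise) {
        if (!sa$fallback) next
        sa2 <- stage_A(q$A)
        y2 <- assemble(stage_S(sa2, q$v_amp), H, q$v_exp, q$e_amp,
                       q$e_exp)
      } else if (i %in% idx_hemo) {
        # only one region's transfer column changes
        r <- i - idx_hemo[1] + 1
        r <- if (r > n) r - n else r
        H2 <- H
        H2[, r] <- hemo_transfer_col(q$decay[r], q$transit[r], omega)
        y2 <- assemble(S, H2, q$v_exp, q$e_amp, q$e_exp)
      }
      J[, i] <- (y2 - g0) / step
    }
    J
  }

  list(predict = predict_theta, jacobian = jacobian_theta)
}
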