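#' Frequency grid for spectral analysis
#'
#' @param freq_hz Strictly increasing vector of positive frequencies (Hz).
#' @return Object of class `frequency_grid` with elements `freq_hz` and
#'   `omega` (angular frequencies, rad/s).
#' @export
frequency_grid <- function(freq_hz) {
  freq_hz <- as.numeric(freq_hz)
  if (any(!is.finite(freq_hz)) || any(freq_hz <= 0)) {
    stop("frequencies must be finite and > 0", call. = FALSE)
  }
  if (any(diff(freq_hz) <= 0)) {
    stop("frequencies must be strictly increasing", call. = FALSE)
  }
  structure(list(freq_hz = freq_hz, omega = 2 * pi * freq_hz),
            class = "frequency_grid")
}

#' Default resting-state analysis grid
#'
#' 32 logarithmically spaced frequencies spanning 1/128 Hz to 0.25 Hz,
#' covering the resting-state band for a sampling interval of about
#' 0.72 s.
#'
#' @param n_points Number of grid points.
#' @param fmin,fmax Band edges in Hz.
#' @export
default_frequency_grid <- function(n_points = 32, fmin = 1 / 128,
                                   fmax = 0.25) {
  frequency_grid(exp(seq(log(fmin), log(fmax), length.out = n_points)))
}

#' Power-law noise spectrum
#'
#' Evaluates `g(w) = exp(log_amp) * w^(-exp(log_exp))` on a frequency
#' grid.  `log_exp = -Inf` is the flat-spectrum convention (exponent 0,
#' white noise).
#'
#' @param log_amp Log-amplitude.
#' @param log_exp Log of the spectral exponent; the implied exponent
#'   `exp(log_exp)` is nonnegative by construction.
#' @param grid A [frequency_grid()].
#' @return Strictly positive numeric vector, one value per grid point.
#' @export
powerlaw_spectrum <- function(log_amp, log_exp, grid) {
  stopifnot(inherits(grid, "frequency_grid"))
  if (any(grid$omega <= 0)) {
    stop("power-law spectrum requires omega > 0", call. = FALSE)
  }
  if (!is.finite(log_amp) || is.na(log_exp) || log_exp == Inf) {
    stop("invalid power-law parameters", call. = FALSE)
  }
  b <- if (identical(log_exp, -Inf)) 0 else exp(log_exp)
  exp(log_amp) * grid$omega^(-b)
}

#' Cross-spectral density container
#'
#' @param grid A [frequency_grid()].
#' @param matrices List of complex Hermitian n-by-n matrices, one per grid
#'   point, or a complex array of dimension `c(n, n, n_freq)`.
#' @param labels Optional region labels.
#' @param check Validate Hermitian symmetry and positive semidefiniteness.
#' @return Object of class `cross_spectra`: `grid`, `csd` (n x n x n_freq
#'   complex array), `labels`.
#' @export
cross_spectra <- function(grid, matrices, labels = NULL, check = TRUE) {
  stopifnot(inherits(grid, "frequency_grid"))
  if (is.list(matrices)) {
    n <- nrow(matrices[[1]])
    csd <- array(0i, dim = c(n, n, length(matrices)))
    for (k in seq_along(matrices)) csd[, , k] <- matrices[[k]]
  } else {
    csd <- matrices
  }
  stopifnot(length(dim(csd)) == 3, dim(csd)[1] == dim(csd)[2],
            dim(csd)[3] == length(grid$omega))
  n <- dim(csd)[1]
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  if (check) {
    for (k in seq_len(dim(csd)[3])) {
      m <- csd[, , k]
      scale <- max(1, max(Mod(m)))
      if (max(Mod(m - Conj(t(m)))) > 1e-8 * scale) {
        stop("cross-spectral matrix not Hermitian at grid point ", k,
             call. = FALSE)
      }
      ev <- eigen((m + Conj(t(m))) / 2, symmetric = TRUE,
                  only.values = TRUE)$values
      if (min(ev) < -1e-8 * scale) {
        stop("cross-spectral matrix not positive semidefinite at grid ",
             "point ", k, " (eigenvalue ", format(min(ev)), ")",
             call. = FALSE)
      }
    }
  }
  structure(list(grid = grid, csd = csd, labels = labels),
            class = "cross_spectra")
}

#' @export
print.cross_spectra <- function(x, ...) {
  cat("<cross_spectra>", dim(x$csd)[1], "regions x",
      dim(x$csd)[3], "frequencies\n")
  invisible(x)
}

# Stack a CSD into the real data-feature vector used by the likelihood:
# per frequency, the real parts of all entries (column-major) followed by
# the imaginary parts.
stack_csd <- function(csd_array) {
  nf <- dim(csd_array)[3]
  out <- vector("list", nf)
  for (k in seq_len(nf)) {
    m <- csd_array[, , k]
    out[[k]] <- c(Re(m), Im(m))
  }
  unlist(out, use.names = FALSE)
}

#' Predicted cross-spectral density of the state-space model
#'
#' The spectral forward model: neuronal fluctuations with power-law
#' spectra `Gv(w)` pass through the network transfer `(iwI - A)^-1`, are
#' filtered by the region-wise hemodynamic transfer `H(w)`, and additive
#' observation noise `Ge(w)` is superimposed:
#' `G(w) = H(w) (iwI - A)^-1 Gv(w) (-iwI - A')^-1 H(w)* + Ge(w)`.
#'
#' @param A Effective connectivity matrix (n x n, Hz); eigenvalues should
#'   have negative real part for a stationary interpretation (a warning,
#'   not an error, is issued otherwise so the likelihood stays evaluable).
#' @param hparams [hemodynamic_params()] for the n regions.
#' @param nparams A [noise_spectra_params()] object.
#' @param grid A [frequency_grid()].
#' @param check Validate the output container invariants.
#' @return A [cross_spectra()] object.
#' @export
predicted_csd <- function(A, hparams, nparams, grid, check = TRUE) {
  A <- as.matrix(A)
  n <- nrow(A)
  stopifnot(ncol(A) == n, inherits(grid, "frequency_grid"))
  if (!all(is.finite(A))) stop("non-finite entries in A", call. = FALSE)
  ev <- eigen(A, only.values = TRUE)$values
  if (max(Re(ev)) >= 0) {
    warning("A is not strictly stable (max Re eigenvalue ",
            format(max(Re(ev))), ")", call. = FALSE)
  }
  H <- hemodynamic_transfer(hparams, grid)
  Gv <- noise_spectra_eval(nparams, grid, "v") # n_freq x n
  Ge <- noise_spectra_eval(nparams, grid, "e")
  csd <- csd_core(A, H, Gv, Ge, grid$omega)
  cross_spectra(grid, csd, check = check)
}

# Inner loop of the spectral forward model, shared by predicted_csd and
# the inversion (which bypasses container validation for speed).
csd_core <- function(A, H, Gv, Ge, omega) {
  n <- nrow(A)
  nf <- length(omega)
  I <- diag(n)
  csd <- array(0i, dim = c(n, n, nf))
  for (k in seq_len(nf)) {
    M <- 1i * omega[k] * I - A
    Mi <- tryCatch(solve(M, I), error = function(e) NULL)
    if (is.null(Mi)) {
      stop("(iwI - A) is numerically singular at frequency ",
           format(omega[k] / (2 * pi)), " Hz", call. = FALSE)
    }
    # S = Mi Gv Mi^H with diagonal Gv; then sandwich with diagonal H.
    S <- (Mi * rep(Gv[k, ], each = n)) %*% Conj(t(Mi))
    G <- (H[k, ] * S) * rep(Conj(H[k, ]), each = n)
    diag(G) <- diag(G) + Ge[k, ]
    csd[, , k] <- G
  }
  csd
}

#' Power-law noise parameters of the spectral model
#'
#' One log-amplitude per region and one shared log-exponent for each of
#' the endogenous neuronal fluctuations (`v`) and the observation error
#' (`e`); cross-region noise spectra are diagonal.
#'
#' @param v_amp,e_amp Per-region log-amplitudes.
#' @param v_exp,e_exp Shared log-exponents (`-Inf` for a flat spectrum).
#' @export
noise_spectra_params <- function(v_amp = 0, v_exp = 0, e_amp = 0,
                                 e_exp = 0) {
  n <- max(length(v_amp), length(e_amp))
  structure(list(v_amp = rep_len(as.numeric(v_amp), n),
                 v_exp = as.numeric(v_exp)[1],
                 e_amp = rep_len(as.numeric(e_amp), n),
                 e_exp = as.numeric(e_exp)[1], n = n),
            class = "noise_spectra_params")
}

noise_spectra_eval <- function(nparams, grid, which = c("v", "e")) {
  which <- match.arg(which)
  amp <- nparams[[paste0(which, "_amp")]]
  ex <- nparams[[paste0(which, "_exp")]]
  vapply(seq_along(amp),
         function(r) powerlaw_spectrum(amp[r], ex, grid),
         numeric(length(grid$omega)))
}

#' Write / read cross-spectra as delimited text
#'
#' Plain-text serialization: a header line with the region labels, then
#' per frequency one block holding the frequency (Hz) and the real and
#' imaginary parts of the matrix at 15 significant digits.
#'
#' @param x A [cross_spectra()] object.
#' @param path File path.
#' @export
write_csd <- function(x, path) {
  stopifnot(inherits(x, "cross_spectra"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# regions: ", paste(x$labels, collapse = "\t")), con)
  nf <- dim(x$csd)[3]
  for (k in seq_len(nf)) {
    writeLines(paste0("freq\t", format(x$grid$freq_hz[k], digits = 15)),
               con)
    m <- x$csd[, , k]
    for (i in seq_len(nrow(m))) {
      writeLines(paste(format(Re(m[i, ]), digits = 15), collapse = "\t"),
                 con)
    }
    for (i in seq_len(nrow(m))) {
      writeLines(paste(format(Im(m[i, ]), digits = 15), collapse = "\t"),
                 con)
    }
  }
  invisible(path)
}

#' @rdname write_csd
#' @export
read_csd <- function(path) {
  lines <- readLines(path)
  labels <- strsplit(sub("^# regions: ", "", lines[1]), "\t")[[1]]
  n <- length(labels)
  body <- lines[-1]
  block <- 1 + 2 * n
  nf <- length(body) / block
  stopifnot(nf == round(nf))
  freqs <- numeric(nf)
  mats <- vector("list", nf)
  for (k in seq_len(nf)) {
    off <- (k - 1) * block
    freqs[k] <- as.numeric(strsplit(body[off + 1], "\t")[[1]][2])
    parse_rows <- function(rows) {
      do.call(rbind, lapply(rows, function(l)
        as.numeric(strsplit(l, "\t")[[1]])))
    }
    re <- parse_rows(body[off + 1 + seq_len(n)])
    im <- parse_rows(body[off + 1 + n + seq_len(n)])
    mats[[k]] <- re + 1i * im
  }
  cross_spectra(frequency_grid(freqs), mats, labels = labels,
                check = FALSE)
}
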