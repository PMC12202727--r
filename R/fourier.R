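# Centered Fourier conventions shared by the Cartesian and gridding recons.
#
# Image grids are centered on the rotation axis with voxel centers at
# half-integer offsets: x_j = (j - 1 - n/2 + 1/2) * dx, j = 1..n (n even).
# k-space grids put DC at index n/2 + 1: k_m = (m - 1 - n/2) / (n * dx),
# in cycles/mm. The helpers below evaluate unnormalized centered DFT sums
#   fft_centered:  S_m = sum_j I_j exp(-2i pi k_m . x_j)
#   ifft_centered: I_j = sum_m S_m exp(+2i pi k_m . x_j)
# via fft() plus per-axis phase ramps, so callers own all physical scaling.

x_axis <- function(n, dx) ((seq_len(n) - 1) - n / 2 + 0.5) * dx

k_axis <- function(n, dx) ((seq_len(n) - 1) - n / 2) / (n * dx)

# Per-axis phase ramp vectors for the centered DFT identities.
centered_phases <- function(n) {
  stopifnot(n %% 2 == 0)
  m <- n / 2
  np <- seq_len(n) - 1
  list(
    pre  = exp(2i * pi * (np - m) * (0.5 - m) / n),  # k-space side
    post = exp(-2i * pi * m * np / n)                # image side, (-1)^j'
  )
}

# Multiply a 1/2/3-D array by the outer product of per-axis complex vectors.
axis_mult <- function(arr, vecs) {
  d <- length(dim(arr) %||% length(arr))
  dm <- dim(arr) %||% length(arr)
  ph <- vecs[[1]]
  if (length(vecs) > 1) for (i in 2:length(vecs)) ph <- outer(ph, vecs[[i]])
  arr * array(ph, dm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Unnormalized centered inverse DFT sum (see header).
ifft_centered <- function(S) {
  dm <- dim(S) %||% length(S)
  ph <- lapply(dm, centered_phases)
  pre <- lapply(ph, `[[`, "pre")
  post <- lapply(ph, `[[`, "post")
  out <- fft(axis_mult(S, pre), inverse = TRUE)
  out <- axis_mult(out, post)
  dim(out) <- dm
  out
}

# Unnormalized centered forward DFT sum.
fft_centered <- function(I) {
  dm <- dim(I) %||% length(I)
  ph <- lapply(dm, centered_phases)
  pre <- lapply(ph, function(p) Conj(p$pre))
  post <- lapply(ph, function(p) Conj(p$post))
  out <- fft(axis_mult(I, post))
  out <- axis_mult(out, pre)
  dim(out) <- dm
  out
}

nrmse <- function(x, ref) sqrt(mean((x - ref)^2)) / sqrt(mean(ref^2))
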