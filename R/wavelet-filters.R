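# Decomposition/reconstruction filter banks for the seven mother wavelets used for
# spectral feature extraction. Coefficients are the standard published values for each
# family (orthogonal banks satisfy dec_lo = rev(rec_lo), rec_hi = (-1)^k dec_lo).
# The discrete Meyer ("dmey") bank is an FIR truncation of the ideal Meyer conjugate
# mirror filter and is synthesised at load time in .dmeyBank(); see the methods vignette
# for the truncation-length choice.

.FILTER_BANKS <- list(
  haar = list(
    dec_lo = c(
    0.7071067811865476, 0.7071067811865476),
    dec_hi = c(
    -0.7071067811865476, 0.7071067811865476),
    rec_lo = c(
    0.7071067811865476, 0.7071067811865476),
    rec_hi = c(
    0.7071067811865476, -0.7071067811865476)),
  db5 = list(
    dec_lo = c(
    0.0033357252854737712, -0.012580751999081999, -0.006241490212798274, 0.07757149384004572,
    -0.032244869584638375, -0.24229488706638203, 0.13842814590132074, 0.7243085284377729,
    0.6038292697971896, 0.16010239797419293),
    dec_hi = c(
    -0.16010239797419293, 0.6038292697971896, -0.7243085284377729, 0.13842814590132074,
    0.24229488706638203, -0.032244869584638375, -0.07757149384004572, -0.006241490212798274,
    0.012580751999081999, 0.0033357252854737712),
    rec_lo = c(
    0.16010239797419293, 0.6038292697971896, 0.7243085284377729, 0.13842814590132074,
    -0.24229488706638203, -0.032244869584638375, 0.07757149384004572, -0.006241490212798274,
    -0.012580751999081999, 0.0033357252854737712),
    rec_hi = c(
    0.0033357252854737712, 0.012580751999081999, -0.006241490212798274, -0.07757149384004572,
    -0.032244869584638375, 0.24229488706638203, 0.13842814590132074, -0.7243085284377729,
    0.6038292697971896, -0.16010239797419293)),
  coif2 = list(
    dec_lo = c(
    -0.000720549445520347, -0.0018232088709110323, 0.005611434819368834, 0.02368017194684777,
    -0.05943441864643109, -0.07648859907828076, 0.4170051844232391, 0.8127236354494135,
    0.3861100668227629, -0.0673725547237256, -0.04146493678687178, 0.01638733646320364),
    dec_hi = c(
    -0.01638733646320364, -0.04146493678687178, 0.0673725547237256, 0.3861100668227629,
    -0.8127236354494135, 0.4170051844232391, 0.07648859907828076, -0.05943441864643109,
    -0.02368017194684777, 0.005611434819368834, 0.0018232088709110323, -0.000720549445520347),
    rec_lo = c(
    0.01638733646320364, -0.04146493678687178, -0.0673725547237256, 0.3861100668227629,
    0.8127236354494135, 0.4170051844232391, -0.07648859907828076, -0.05943441864643109,
    0.02368017194684777, 0.005611434819368834, -0.0018232088709110323, -0.000720549445520347),
    rec_hi = c(
    -0.000720549445520347, 0.0018232088709110323, 0.005611434819368834, -0.02368017194684777,
    -0.05943441864643109, 0.07648859907828076, 0.4170051844232391, -0.8127236354494135,
    0.3861100668227629, 0.0673725547237256, -0.04146493678687178, -0.01638733646320364)),
  sym2 = list(
    dec_lo = c(
    -0.12940952255092145, 0.22414386804185735, 0.836516303737469, 0.48296291314469025),
    dec_hi = c(
    -0.48296291314469025, 0.836516303737469, -0.22414386804185735, -0.12940952255092145),
    rec_lo = c(
    0.48296291314469025, 0.836516303737469, 0.22414386804185735, -0.12940952255092145),
    rec_hi = c(
    -0.12940952255092145, -0.22414386804185735, 0.836516303737469, -0.48296291314469025)),
  `bior1.5` = list(
    dec_lo = c(
    0.016572815184059706, -0.016572815184059706, -0.12153397801643785, 0.12153397801643785,
    0.7071067811865476, 0.7071067811865476, 0.12153397801643785, -0.12153397801643785,
    -0.016572815184059706, 0.016572815184059706),
    dec_hi = c(
    -0.0, 0.0, -0.0, 0.0, -0.7071067811865476, 0.7071067811865476, -0.0, 0.0, -0.0, 0.0),
    rec_lo = c(
    0.0, 0.0, 0.0, 0.0, 0.7071067811865476, 0.7071067811865476, 0.0, 0.0, 0.0, 0.0),
    rec_hi = c(
    0.016572815184059706, 0.016572815184059706, -0.12153397801643785, -0.12153397801643785,
    0.7071067811865476, -0.7071067811865476, 0.12153397801643785, 0.12153397801643785,
    -0.016572815184059706, -0.016572815184059706)),
  `rbio1.1` = list(
    dec_lo = c(
    0.7071067811865476, 0.7071067811865476),
    dec_hi = c(
    -0.7071067811865476, 0.7071067811865476),
    rec_lo = c(
    0.7071067811865476, 0.7071067811865476),
    rec_hi = c(
    0.7071067811865476, -0.7071067811865476)),
  placeholder = NULL)
.FILTER_BANKS$placeholder <- NULL


# Synthesise the discrete Meyer lowpass filter by frequency sampling of the ideal Meyer
# conjugate mirror filter and centred truncation. The ideal filter is IIR; common FIR
# truncations (62 or 102 taps) leave a perfect-reconstruction defect of ~5e-3 / ~4e-6.
# A 402-tap truncation brings the defect below 1e-8, which is the fidelity this package
# commits to for round-trip decomposition; the cost is that dmey supports fewer
# decomposition levels on short signals (length must stay >= 402).
.dmeyLowpass <- function(ntaps = 402L, grid = 2^14) {
  w <- 2 * pi * seq(0L, grid - 1L) / grid
  w <- ifelse(w > pi, w - 2 * pi, w)           # frequencies in (-pi, pi]
  aw <- abs(w)
  x <- pmin(pmax(3 * aw / pi - 1, 0), 1)
  nu <- x^4 * (35 - 84 * x + 70 * x^2 - 20 * x^3)
  H <- numeric(grid)
  H[aw <= pi / 3] <- sqrt(2)
  mid <- aw > pi / 3 & aw <= 2 * pi / 3
  H[mid] <- sqrt(2) * cos(pi / 2 * nu[mid])
  h <- Re(stats::fft(H, inverse = TRUE)) / grid
  # fftshift, then centred truncation to ntaps
  h <- c(h[(grid / 2 + 1):grid], h[1:(grid / 2)])
  ctr <- grid / 2
  h[(ctr - ntaps / 2 + 1):(ctr + ntaps / 2)]
}

.dmeyBank <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec_lo <- .dmeyLowpass()
      L <- length(rec_lo)
      dec_lo <- rev(rec_lo)
      rec_hi <- (-1)^(seq_len(L) - 1L) * dec_lo
      dec_hi <- rev(rec_hi)
      cache <<- list(dec_lo = dec_lo, dec_hi = dec_hi,
                     rec_lo = rec_lo, rec_hi = rec_hi)
    }
    cache
  }
})

#' Mother wavelets available for spectral decomposition
#'
#' @return Character vector of the seven supported mother-wavelet names.
#' @export
#' @examples
#' motherWavelets()
motherWavelets <- function() {
  c("haar", "db5", "dmey", "coif2", "sym2", "bior1.5", "rbio1.1")
}

# Return the four-filter bank (dec_lo, dec_hi, rec_lo, rec_hi) for a wavelet name.
.waveletBank <- function(wavelet) {
  wavelet <- match.arg(wavelet, motherWavelets())
  if (wavelet == "dmey") return(.dmeyBank())
  .FILTER_BANKS[[wavelet]]
}

#' Decomposition filter length of a mother wavelet
#'
#' @param wavelet One of \code{motherWavelets()}.
#' @return Integer number of filter taps (e.g. 10 for \code{"db5"}).
#' @export
#' @examples
#' filterLength("db5")
filterLength <- function(wavelet) {
  length(.waveletBank(wavelet)$dec_lo)
}
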