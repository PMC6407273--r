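#' QQ plot of association p-values
#'
#' Observed versus expected -log10 p-values under the uniform null, with the
#' genomic inflation factor in the title.
#'
#' @param p Vector of p-values.
#' @param main Plot title prefix.
#' @return Invisibly, NULL. Base-graphics side effect.
#' @export
qq_plot <- function(p, main = "QQ plot") {
  p <- sort(p[!is.na(p)])
  n <- length(p)
  exp_q <- -log10((seq_len(n) - 0.5) / n)
  graphics::plot(exp_q, -log10(p), pch = 20, cex = 0.4,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)),
                 main = sprintf("%s (lambda = %.3f)", main, genomic_lambda(p)))
  graphics::abline(0, 1, col = "red")
  invisible(NULL)
}

#' Manhattan plot of a scan
#'
#' Minimal chromosome-coloured scatter of -log10 p-values by genomic order.
#'
#' @param scan A `scan_summary`.
#' @param threshold Optional horizontal reference line (p-value scale).
#' @return Invisibly, NULL. Base-graphics side effect.
#' @export
manhattan_plot <- function(scan, threshold = NULL) {
  r <- scan$results[!is.na(scan$results$p), ]
  r <- r[order(r$chr, r$pos), ]
  x <- seq_len(nrow(r))
  graphics::plot(x, -log10(r$p), col = c("grey30", "steelblue")[r$chr %% 2 + 1],
                 pch = 20, cex = 0.4, xlab = "SNP (genomic order)",
                 ylab = expression(-log[10](p)),
                 main = sprintf("%s / %s-smokers", scan$spec$definition,
                                scan$spec$stratum))
  if (!is.null(threshold)) graphics::abline(h = -log10(threshold), col = "red", lty = 2)
  invisible(NULL)
}
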