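# Brute-force two-factor within-subject sums of squares, written
# independently of the package implementation and used as the F-statistic
# oracle.
bruteForceRm <- function(tab, metric) {
  y <- tab[[metric]]
  s <- factor(tab$subject); m <- factor(tab$muscle); l <- factor(tab$level)
  S <- nlevels(s); M <- nlevels(m); L <- nlevels(l)
  g <- mean(y)
  ym <- tapply(y, m, mean); yl <- tapply(y, l, mean); ys <- tapply(y, s, mean)
  yml <- tapply(y, list(m, l), mean)
  ysm <- tapply(y, list(s, m), mean)
  ysl <- tapply(y, list(s, l), mean)
  ssM <- S * L * sum((ym - g)^2)
  ssL <- S * M * sum((yl - g)^2)
  ssML <- S * sum((sweep(sweep(yml, 1, ym, "-"), 2, yl, "-") + g)^2)
  ssSM <- L * sum((sweep(sweep(ysm, 1, ys, "-"), 2, ym, "-") + g)^2)
  ssSL <- M * sum((sweep(sweep(ysl, 1, ys, "-"), 2, yl, "-") + g)^2)
  ssS <- M * L * sum((ys - g)^2)
  ssT <- sum((y - g)^2)
  ssSML <- ssT - ssM - ssL - ssML - ssS - ssSM - ssSL
  Fm <- (ssM / (M - 1)) / (ssSM / ((S - 1) * (M - 1)))
  Fl <- (ssL / (L - 1)) / (ssSL / ((S - 1) * (L - 1)))
  Fml <- (ssML / ((M - 1) * (L - 1))) /
    (ssSML / ((S - 1) * (M - 1) * (L - 1)))
  c(muscle = Fm, level = Fl, `muscle:level` = Fml)
}
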