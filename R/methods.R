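#' @rdname ChromatinMap-class
#' @export
setMethod("stateFragments", "ChromatinMap", function(x) x@fragments)

#' @rdname ChromatinMap-class
#' @export
setMethod("chromatinDomains", "ChromatinMap", function(x) x@domains)

#' @rdname ChromatinMap-class
#' @export
setMethod("chromLengths", "ChromatinMap",
          function(x) seqlengths(x@fragments))

#' @rdname ChromatinMap-class
#' @export
setMethod("mappedLength", "ChromatinMap",
          function(x) sum(as.numeric(width(x@fragments[x@fragments$state != "gap"]))))

#' @rdname ChromatinMap-class
#' @export
setMethod("gapLength", "ChromatinMap",
          function(x) sum(as.numeric(width(x@fragments[x@fragments$state == "gap"]))))

setMethod("show", "ChromatinMap", function(object) {
  sl <- chromLengths(object)
  cat("ChromatinMap with", length(sl), "chromosome(s), total span",
      format(sum(as.numeric(sl)), big.mark = ","), "bp\n")
  cat("  mapped:", format(mappedLength(object), big.mark = ","),
      "bp; gaps:", format(gapLength(object), big.mark = ","), "bp\n")
  cat("  fragments:", length(object@fragments),
      "; domains:", length(object@domains),
      if (!length(object@domains)) "(run mergeDomains())" else "", "\n")
  tb <- table(object@fragments$state)
  cat("  fragment counts:",
      paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
})

#' @rdname Arrangement-class
#' @export
setMethod("domainLengths", "Arrangement", function(x) x@domainLengths)

#' @rdname Arrangement-class
#' @export
setMethod("spacerLengths", "Arrangement", function(x) x@spacerLengths)

setMethod("length", "Arrangement", function(x) length(x@domainLengths))

setMethod("show", "Arrangement", function(object) {
  cat("Arrangement on", object@chrom,
      "(length", format(object@chromLength, big.mark = ","), "bp):",
      length(object@domainLengths), "domains,",
      length(object@spacerLengths), "spacers\n")
})

#' @rdname ShuffleResult-class
#' @export
setMethod("pEnrich", "ShuffleResult", function(x) x@pEnrich)

#' @rdname ShuffleResult-class
#' @export
setMethod("pDeplete", "ShuffleResult", function(x) x@pDeplete)

#' @rdname ShuffleResult-class
#' @export
setMethod("nullMoments", "ShuffleResult",
          function(x) c(mean = x@nullMean, sd = x@nullSd))

setMethod("show", "ShuffleResult", function(object) {
  cat("ShuffleResult [", object@chrom, ", statistic=", object@statistic,
      ", M=", object@M, "]\n", sep = "")
  cat(sprintf("  observed %.6g vs null %.6g +/- %.6g\n",
              object@observed, object@nullMean, object@nullSd))
  cat(sprintf("  p_enrich = %.3g, p_deplete = %.3g (%s%s)\n",
              object@pEnrich, object@pDeplete, object@method,
              if (object@degenerate) ", degenerate null" else ""))
})

#' Flatten a ShuffleResult to a one-row data.frame
#'
#' @param x a [ShuffleResult-class].
#' @param row.names,optional,... passed for S3 compatibility; unused.
#' @return a one-row \code{data.frame} with all result fields.
#' @exportS3Method base::as.data.frame
#' @export
as.data.frame.ShuffleResult <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(chrom = x@chrom, statistic = x@statistic,
             observed = x@observed, null_mean = x@nullMean,
             null_sd = x@nullSd, M = x@M,
             count_ge = x@countGE, count_le = x@countLE,
             p_enrich = x@pEnrich, p_deplete = x@pDeplete,
             p_enrich_add1 = x@pEnrichAdd1,
             p_deplete_add1 = x@pDepleteAdd1,
             method = x@method, degenerate = x@degenerate,
             stringsAsFactors = FALSE)
}
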