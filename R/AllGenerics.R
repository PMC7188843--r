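#' @rdname MqtlTable-class
#' @param object,x an object.
#' @export
setGeneric("mqtlStats", function(x) standardGeneric("mqtlStats"))

#' @rdname MqtlTable-class
#' @export
setGeneric("probeInfo", function(x) standardGeneric("probeInfo"))

#' @rdname MqtlTable-class
#' @export
setGeneric("nRejected", function(x) standardGeneric("nRejected"))

#' @rdname MqtlTable-class
#' @param probe a probe id.
#' @export
setGeneric("cisStats", function(x, probe) standardGeneric("cisStats"))

#' @rdname LdMatrix-class
#' @export
setGeneric("ldSnps", function(x) standardGeneric("ldSnps"))

#' @rdname LdMatrix-class
#' @export
setGeneric("ldCor", function(x) standardGeneric("ldCor"))

#' @rdname LdMatrix-class
#' @export
setGeneric("ldAlleles", function(x) standardGeneric("ldAlleles"))

#' @rdname PaiSet-class
#' @export
setGeneric("paiRecords", function(x) standardGeneric("paiRecords"))

#' @rdname PaiSet-class
#' @export
setGeneric("paiSignificant", function(x) standardGeneric("paiSignificant"))

#' @rdname PaiSet-class
#' @export
setGeneric("nTests", function(x) standardGeneric("nTests"))

#' @rdname EnrichmentResult-class
#' @export
setGeneric("enrichFold", function(x) standardGeneric("enrichFold"))

#' @rdname EnrichmentResult-class
#' @export
setGeneric("enrichP", function(x) standardGeneric("enrichP"))

#' @rdname EnrichmentResult-class
#' @export
setGeneric("nullValues", function(x) standardGeneric("nullValues"))


#' @rdname MqtlTable-class
#' @export
setMethod("mqtlStats", "MqtlTable", function(x) x@stats)

#' @rdname MqtlTable-class
#' @export
setMethod("probeInfo", "MqtlTable", function(x) x@probes)

#' @rdname MqtlTable-class
#' @export
setMethod("nRejected", "MqtlTable", function(x) x@nRejected)

#' @rdname MqtlTable-class
#' @export
setMethod("cisStats", "MqtlTable", function(x, probe) {
  x@stats[x@stats$probe_id == probe, , drop = FALSE]
})

#' @rdname LdMatrix-class
#' @export
setMethod("ldSnps", "LdMatrix", function(x) x@snps)

#' @rdname LdMatrix-class
#' @export
setMethod("ldCor", "LdMatrix", function(x) {
  m <- x@r
  dimnames(m) <- list(x@snps, x@snps)
  m
})

#' @rdname LdMatrix-class
#' @export
setMethod("ldAlleles", "LdMatrix", function(x) {
  data.frame(snp_id = x@snps, a1 = x@a1, a2 = x@a2, stringsAsFactors = FALSE)
})

#' @rdname PaiSet-class
#' @export
setMethod("paiRecords", "PaiSet", function(x) x@records)

#' @rdname PaiSet-class
#' @export
setMethod("paiSignificant", "PaiSet", function(x) {
  r <- x@records
  if (!nrow(r)) return(r)
  r[!is.na(r$is_pai) & r$is_pai, , drop = FALSE]
})

#' @rdname PaiSet-class
#' @export
setMethod("nTests", "PaiSet", function(x) x@nTests)

#' @rdname EnrichmentResult-class
#' @export
setMethod("enrichFold", "EnrichmentResult", function(x) x@fold)

#' @rdname EnrichmentResult-class
#' @export
setMethod("enrichP", "EnrichmentResult", function(x) x@empiricalP)

#' @rdname EnrichmentResult-class
#' @export
setMethod("nullValues", "EnrichmentResult", function(x) x@nullValues)


setMethod("show", "MqtlTable", function(object) {
  cat("MqtlTable:", length(unique(object@stats$probe_id)), "probes,",
      nrow(object@stats), "probe-SNP rows",
      sprintf("(cis window %g bp)\n", object@cisWindow))
  if (object@nRejected > 0L)
    cat("  rows rejected on read:", object@nRejected, "\n")
})

setMethod("show", "LdMatrix", function(object) {
  cat("LdMatrix:", length(object@snps), "SNPs; mean |r| off-diagonal =",
      if (length(object@snps) > 1)
        sprintf("%.3f", mean(abs(object@r[upper.tri(object@r)]))) else "NA",
      "\n")
})

setMethod("show", "PaiSet", function(object) {
  r <- object@records
  cat("PaiSet:", nrow(r), "exposure-outcome tests,", object@nTests,
      "with computed SMR p\n")
  if (nrow(r) && "is_pai" %in% names(r))
    cat("  significant PAIs:", sum(r$is_pai, na.rm = TRUE), "\n")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(
    "EnrichmentResult (%s): observed = %.4g, null mean = %.4g (sd %.4g)\n",
    object@direction, object@observed, mean(object@nullValues),
    sd(object@nullValues)))
  cat(sprintf("  fold = %.3f, empirical p %s %.4g (%d null sets)\n",
              object@fold, if (object@truncated) "<" else "=",
              if (object@truncated) 1 / length(object@nullValues)
              else object@empiricalP,
              length(object@nullValues)))
})
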