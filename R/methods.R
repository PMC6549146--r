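#' @rdname MethylSet
#' @export
setMethod("betaValues", "MethylSet", function(object) assay(object, "beta"))

#' @rdname MethylSet
#' @export
setMethod("detectionP", "MethylSet",
          function(object) assay(object, "detectionP"))

#' @rdname MethylSet
#' @export
setMethod("probeManifest", "MethylSet", function(object) {
  as.data.frame(rowData(object))
})

#' @rdname MethylSet
#' @export
setMethod("sampleSheet", "MethylSet", function(object) {
  as.data.frame(colData(object))
})

setMethod("show", "MethylSet", function(object) {
  cat("MethylSet:", nrow(object), "probes x", ncol(object), "samples\n")
  man <- rowData(object)
  cat(sprintf("  design: %d type I / %d type II; %d bisulfite controls\n",
              sum(man$design_type == "I"), sum(man$design_type == "II"),
              sum(man$is_bisulfite_control)))
  callNextMethod()
})

#' @rdname QCReport-class
#' @export
setMethod("removedProbes", "QCReport", function(object) object@removedProbes)

#' @rdname QCReport-class
#' @export
setMethod("removedSamples", "QCReport",
          function(object) object@removedSamples)

#' @rdname QCReport-class
#' @export
setMethod("bisulfiteEfficiency", "QCReport",
          function(object) object@bisulfiteEfficiency)

setMethod("show", "QCReport", function(object) {
  cat("QCReport\n")
  cat(sprintf("  probes:  %d -> %d (%d removed)\n", object@probesBefore,
              object@probesAfter, nrow(object@removedProbes)))
  if (nrow(object@removedProbes)) {
    tab <- table(object@removedProbes$reason)
    cat("   ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf("  samples: %d -> %d (%d removed)\n", object@samplesBefore,
              object@samplesAfter, nrow(object@removedSamples)))
})

setMethod("show", "ReplicationReport", function(object) {
  cat("ReplicationReport\n")
  cat(sprintf("  primary significant : %d\n",
              length(object@primarySignificant)))
  cat(sprintf("  tested in replication: %d (%d excluded)\n",
              length(object@tested), nrow(object@excluded)))
  cat(sprintf("  replicated (p < alpha, same direction): %d\n",
              length(object@replicated)))
  if (length(object@combinedSignificant))
    cat(sprintf("  combined-cohort significant: %d\n",
                length(object@combinedSignificant)))
})

#' @rdname ReplicationReport-class
#' @param object a `ReplicationReport`.
#' @export
setGeneric("replicatedProbes",
           function(object) standardGeneric("replicatedProbes"))

#' @rdname ReplicationReport-class
#' @export
setMethod("replicatedProbes", "ReplicationReport",
          function(object) object@replicated)
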