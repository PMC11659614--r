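#' @include AllClasses.R
NULL

#' Accessors for Recording objects
#'
#' `signals()` returns the samples x channels matrix, `samplingRate()`
#' the rate in Hz, `stateLabels()` the per-sample labels (length 0 if
#' unlabeled), `nSamples()`/`nChannels()` the dimensions.
#'
#' @param x a [Recording-class] (for `samplingRate`, also an
#'   [ACFEstimate-class] or [SimulationResult-class]).
#' @return the slot content described above.
#' @name recording-accessors
#' @examples
#' rec <- Recording(matrix(rnorm(100), 50, 2), fs = 20)
#' samplingRate(rec); nChannels(rec)
NULL

#' @rdname recording-accessors
#' @export
setGeneric("signals", function(x) standardGeneric("signals"))
#' @rdname recording-accessors
#' @export
setMethod("signals", "Recording", function(x) x@signals)

#' @rdname recording-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname recording-accessors
#' @export
setMethod("samplingRate", "Recording", function(x) x@fs)
#' @rdname recording-accessors
#' @export
setMethod("samplingRate", "ACFEstimate", function(x) x@fs)
#' @rdname recording-accessors
#' @export
setMethod("samplingRate", "SimulationResult", function(x) x@fs)

#' @rdname recording-accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
#' @rdname recording-accessors
#' @export
setMethod("stateLabels", "Recording", function(x) x@labels)

#' @rdname recording-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname recording-accessors
#' @export
setMethod("nSamples", "Recording", function(x) nrow(x@signals))

#' @rdname recording-accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname recording-accessors
#' @export
setMethod("nChannels", "Recording", function(x) ncol(x@signals))

#' Accessors for Connectome objects
#'
#' `couplingMatrix()` returns the square coupling matrix, `nRegions()`
#' the region count (also defined for simulation results), and
#' `recurrentStrength()` the diagonal (recurrent connections).
#'
#' @param x a [Connectome-class] (for `nRegions`, also a
#'   [SimulationResult-class]).
#' @return the slot content described above.
#' @name connectome-accessors
#' @examples
#' con <- genConnectome(10, seed = 1)
#' nRegions(con); range(recurrentStrength(con))
NULL

#' @rdname connectome-accessors
#' @export
setGeneric("couplingMatrix", function(x) standardGeneric("couplingMatrix"))
#' @rdname connectome-accessors
#' @export
setMethod("couplingMatrix", "Connectome", function(x) x@W)

#' @rdname connectome-accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))
#' @rdname connectome-accessors
#' @export
setMethod("nRegions", "Connectome", function(x) nrow(x@W))
#' @rdname connectome-accessors
#' @export
setMethod("nRegions", "SimulationResult", function(x) nrow(x@rates))

#' @rdname connectome-accessors
#' @export
setGeneric("recurrentStrength",
           function(x) standardGeneric("recurrentStrength"))
#' @rdname connectome-accessors
#' @export
setMethod("recurrentStrength", "Connectome", function(x) diag(x@W))

#' Accessors for SimulationResult objects
#'
#' `firingRates()` returns the regions x time rate matrix (post
#' transient), `appliedInput()` the external-input trace actually
#' applied, and `simParams()` the parameter snapshot of the run.
#'
#' @param x a [SimulationResult-class].
#' @return the slot content described above.
#' @name simulation-accessors
NULL

#' @rdname simulation-accessors
#' @export
setGeneric("firingRates", function(x) standardGeneric("firingRates"))
#' @rdname simulation-accessors
#' @export
setMethod("firingRates", "SimulationResult", function(x) x@rates)

#' @rdname simulation-accessors
#' @export
setGeneric("appliedInput", function(x) standardGeneric("appliedInput"))
#' @rdname simulation-accessors
#' @export
setMethod("appliedInput", "SimulationResult", function(x) x@input)

#' @rdname simulation-accessors
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))
#' @rdname simulation-accessors
#' @export
setMethod("simParams", "SimulationResult", function(x) x@params)

#' Accessors for ACFEstimate objects
#'
#' `acfValues()` returns the correlation values, `acfLags()` the integer
#' lags in samples.
#'
#' @param x an [ACFEstimate-class].
#' @return numeric (`acfValues`) or integer (`acfLags`) vector.
#' @name acf-accessors
NULL

#' @rdname acf-accessors
#' @export
setGeneric("acfValues", function(x) standardGeneric("acfValues"))
#' @rdname acf-accessors
#' @export
setMethod("acfValues", "ACFEstimate", function(x) x@acf)

#' @rdname acf-accessors
#' @export
setGeneric("acfLags", function(x) standardGeneric("acfLags"))
#' @rdname acf-accessors
#' @export
setMethod("acfLags", "ACFEstimate", function(x) x@lags)
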