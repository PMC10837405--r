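# Classed error conditions so callers can distinguish failure modes
# (empty ROI vs grid mismatch vs bad metadata) without parsing messages.

abort_suvhist <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "suvhist_error"), call = call))
}

abort_validation <- function(message) abort_suvhist(message, "suvhist_validation_error")
abort_empty_roi <- function(message) abort_suvhist(message, "suvhist_empty_roi_error")
abort_grid <- function(message) abort_suvhist(message, "suvhist_grid_error")
abort_io <- function(message) abort_suvhist(message, "suvhist_io_error")
abort_placement <- function(message) abort_suvhist(message, "suvhist_placement_error")
abort_dimensionality <- function(message) abort_suvhist(message, "suvhist_dimensionality_error")
abort_undefined_ratio <- function(message) abort_suvhist(message, "suvhist_undefined_ratio_error")
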