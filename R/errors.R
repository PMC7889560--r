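# Classed conditions so callers can distinguish failure modes programmatically.
# All inherit "surrofrax_error".

sf_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "surrofrax_error"), call = call))
}

sf_format_error     <- function(msg) sf_stop(msg, "surrofrax_format_error")
sf_banding_error    <- function(msg) sf_stop(msg, "surrofrax_banding_error")
sf_validation_error <- function(msg) sf_stop(msg, "surrofrax_validation_error")
sf_alignment_error  <- function(msg) sf_stop(msg, "surrofrax_alignment_error")
sf_domain_error     <- function(msg) sf_stop(msg, "surrofrax_domain_error")
sf_config_error     <- function(msg) sf_stop(msg, "surrofrax_config_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
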