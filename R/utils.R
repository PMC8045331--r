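# Classed error conditions so callers can distinguish failure modes.
ctvStop <- function(subclass, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(subclass, "ctvMargins_error")))
}

ctvWarn <- function(subclass, msg) {
  warning(warningCondition(msg, class = c(subclass, "ctvMargins_warning")))
}

# Coerce a direction given as DirectionSpec, label string, or numeric(3).
asDirectionSpec <- function(direction, routeClass = "unspecified") {
  if (is(direction, "DirectionSpec")) return(direction)
  if (is.character(direction) && length(direction) == 1L)
    return(directionFromLabel(direction, routeClass = routeClass))
  if (is.numeric(direction) && length(direction) == 3L)
    return(DirectionSpec("custom", vector = direction, routeClass = routeClass))
  ctvStop("ctv_label_parse",
          "direction must be a DirectionSpec, a label string, or numeric(3)")
}

vnorm <- function(v) sqrt(sum(v^2))
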