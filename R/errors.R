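# Classed conditions so callers (and tests) can distinguish validation
# failures without matching on message text. Every class also inherits
# "codonMinMaxError".

.cmStop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "codonMinMaxError")))
}

.frameError          <- function(msg) .cmStop("frameError", msg)
.alphabetError       <- function(msg) .cmStop("alphabetError", msg)
.prematureStopError  <- function(msg) .cmStop("prematureStopError", msg)
.tooShortError       <- function(msg) .cmStop("sequenceTooShortError", msg)
.alignmentError      <- function(msg) .cmStop("alignmentError", msg)
.completenessError   <- function(msg) .cmStop("completenessError", msg)
.formatError         <- function(msg) .cmStop("formatError", msg)
.degenerateFamilyError <- function(msg) .cmStop("degenerateFamilyError", msg)
.zeroIntensityError  <- function(msg) .cmStop("zeroIntensityError", msg)
.domainError         <- function(msg) .cmStop("domainError", msg)
.pairingError        <- function(msg) .cmStop("pairingError", msg)
.fitError            <- function(msg) .cmStop("fitError", msg)
.manifestError       <- function(msg) .cmStop("manifestError", msg)
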