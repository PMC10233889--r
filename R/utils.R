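#' @keywords internal
"_PACKAGE"

#' @importFrom stats phyper pt pnorm rnbinom rnorm runif lm glm coef vcov
#'   p.adjust setNames gaussian
#' @importFrom utils read.delim write.table head
NULL

# geometric mean; x must be strictly positive
geomean <- function(x) exp(mean(log(x)))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# mechanism flag strings are semicolon-joined; "." means none
split_flags <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || s == "." || s == "") character(0)
    else strsplit(s, ";", fixed = TRUE)[[1]]
  })
}

join_flags <- function(flags) {
  vapply(flags, function(f) if (length(f) == 0) "." else paste(f, collapse = ";"),
         character(1))
}

GENOTYPE_LEVELS <- c("WT", "Y537S", "D538G", "L536P")
MECHANISM_FLAGS <- c("constitutive", "er_binding", "accessibility", "unexplained")
STATUS_LEVELS <- c("gained", "lost", "shared")

# strict non-negative integer check for count matrices (tolerates integer-valued doubles)
is_count <- function(x) {
  is.numeric(x) & !is.na(x) & x >= 0 & x == round(x)
}
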