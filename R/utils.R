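#' @keywords internal
"_PACKAGE"

#' @importFrom stats as.dist cophenetic cor cutree dist hclust lm.fit
#'   plogis pnorm pt qlogis quantile rbinom rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv
NULL

# classed error helper so callers/tests can match on condition class
pr_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "phylorealms_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

pr_check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    pr_stop(sprintf("`%s` must be a single integer >= %d", name, min),
            "invalid_argument")
  as.integer(x)
}

# derive a bounded child seed from a master seed and a stage offset;
# kept below 2^31 so it is a valid R integer seed
pr_child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}
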