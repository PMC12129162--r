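# The four behavioral types. Integer codes 1..4 are used throughout the
# grids; single-character codes are used in plain-text snapshots.
STRATEGIES <- c("CN", "DN", "CP", "DP")
STRATEGY_CHARS <- c(CN = "C", DN = "D", CP = "P", DP = "Q")
COOPERATES <- c(CN = TRUE, DN = FALSE, CP = TRUE, DP = FALSE)
PUNISHES <- c(CN = FALSE, DN = FALSE, CP = TRUE, DP = TRUE)

#' Strategy labels of the two-stage game
#'
#' The four strategies combine a first-stage move (cooperate `C` / defect
#' `D`) with a second-stage choice (punish defectors `P` / abstain `N`):
#' `CN`, `DN`, `CP`, `DP`. Integer codes 1--4 in lattice grids follow this
#' order.
#'
#' @return `strategy_labels()` returns the character vector
#'   `c("CN", "DN", "CP", "DP")`. `strategy_table()` returns a data frame
#'   with one row per strategy and logical columns `cooperates` and
#'   `punishes`.
#' @examples
#' strategy_table()
#' @export
strategy_labels <- function() STRATEGIES

#' @rdname strategy_labels
#' @export
strategy_table <- function() {
  data.frame(
    label = STRATEGIES,
    code = seq_along(STRATEGIES),
    cooperates = unname(COOPERATES),
    punishes = unname(PUNISHES)
  )
}

strategy_code <- function(label) {
  code <- match(label, STRATEGIES)
  if (anyNA(code)) {
    stop("unknown strategy label(s): ",
         paste(label[is.na(code)], collapse = ", "), call. = FALSE)
  }
  code
}
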