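## Classed error conditions used throughout the package.  Every error raised
## by cttasurv carries class c("cttasurv_<what>", "cttasurv_error", ...), so
## callers can field specific failure modes (empty ROI, degenerate histogram,
## ...) without string matching.
ctta_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("cttasurv_", class), "cttasurv_error"),
                      call = call))
}

ctta_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(paste0("cttasurv_", class),
                                          "cttasurv_warning")))
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

## Canonical spatial-scale set: 0 is the unfiltered control, 2-6 mm are the
## LoG feature radii (fine = 2, medium = 3-5, coarse = 6).
SSF_SCALES <- c(0, 2, 3, 4, 5, 6)

scale_col <- function(ssf) paste0("k", ssf)
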