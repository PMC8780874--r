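#' Build group-aware fold assignments
#'
#' Rows sharing a grouping unit (the \code{groupKey} columns within one
#' sample type, where a sample type is a (variety, robusta_fraction,
#' form) combination) are always assigned to the same fold.  For
#' \code{kfold_grouped} schemes the units of each sample type are
#' shuffled deterministically under the scheme's seed and dealt
#' round-robin over the k folds, which stratifies folds by sample type.
#' For \code{leave_group_out} every unit is its own fold.
#'
#' @param x a \linkS4class{SpectraSet} (or its metadata data.frame).
#' @param scheme a \linkS4class{CVScheme}.
#' @return integer vector of fold ids, one per spectrum.
#' @export
makeFolds <- function(x, scheme) {
  meta <- if (is(x, "SpectraSet")) as.data.frame(sampleData(x))
          else as.data.frame(x)
  validObject(scheme)
  stype <- interaction(meta$variety, meta$robusta_fraction, meta$form,
                       drop = TRUE)
  unit <- do.call(interaction,
                  c(list(stype), meta[scheme@groupKey], list(drop = TRUE)))
  if (scheme@kind == "leave_group_out")
    return(as.integer(factor(unit, levels = unique(unit))))
  folds <- integer(nrow(meta))
  set.seed(scheme@seed)
  for (st in sort(unique(as.character(stype)))) {
    rows <- which(as.character(stype) == st)
    units <- unique(as.character(unit[rows]))
    units <- sample(units)
    fold_of <- setNames(rep_len(seq_len(scheme@k), length(units)), units)
    folds[rows] <- fold_of[as.character(unit[rows])]
  }
  folds
}
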