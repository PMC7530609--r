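#' Sex-chromosome karyotype
#'
#' Identifies a sample by its sex-chromosome complement. The five karyotypes
#' of interest (X0, XX, XY, XXY, XYY) differ widely in repetitive DNA because
#' the Y is almost entirely heterochromatic; custom complements are allowed as
#' long as at least one X is present.
#'
#' @param label One of `"X0"`, `"XX"`, `"XY"`, `"XXY"`, `"XYY"`, or a custom
#'   label (then `n_X`/`n_Y` must be given).
#' @param n_X,n_Y X and Y counts; derived from `label` when omitted.
#' @param autosome_ploidy Autosomal copy number (default 2).
#' @return Object of class `karyotype_spec`.
#' @export
karyotype_spec <- function(label, n_X = NULL, n_Y = NULL, autosome_ploidy = 2L) {
  known <- list(X0 = c(1L, 0L), XX = c(2L, 0L), XY = c(1L, 1L),
                XXY = c(2L, 1L), XYY = c(1L, 2L))
  if (label %in% names(known)) {
    counts <- known[[label]]
    if (is.null(n_X)) n_X <- counts[1]
    if (is.null(n_Y)) n_Y <- counts[2]
    if (n_X != counts[1] || n_Y != counts[2])
      stop("label ", label, " inconsistent with n_X/n_Y")
  }
  if (is.null(n_X) || is.null(n_Y))
    stop("custom karyotype label needs explicit n_X and n_Y")
  if (n_X < 1) stop("n_X must be >= 1")
  if (n_Y < 0) stop("n_Y must be >= 0")
  structure(list(label = label, n_X = as.integer(n_X), n_Y = as.integer(n_Y),
                 autosome_ploidy = as.integer(autosome_ploidy)),
            class = "karyotype_spec")
}

#' @export
print.karyotype_spec <- function(x, ...) {
  cat(sprintf("karyotype %s (n_X=%d, n_Y=%d, autosomes %dn)\n",
              x$label, x$n_X, x$n_Y, x$autosome_ploidy))
  invisible(x)
}

#' Genome size from flow-cytometry fluorescence
#'
#' Diploid genome size is estimated by multiplying the genome size of an
#' internal standard (default: the 328 Mb *D. virilis* diploid reference) by
#' the ratio of propidium-iodide fluorescence of the unknown sample to the
#' standard.
#'
#' @param f_sample Fluorescence of the unknown karyotype (mode of the peak).
#' @param f_standard Fluorescence of the co-prepared standard.
#' @param standard_size_mb Known genome size of the standard in Mb
#'   (default 328).
#' @return Estimated genome size in Mb (vectorized over `f_sample`).
#' @export
genome_size_from_fluorescence <- function(f_sample, f_standard,
                                          standard_size_mb = 328) {
  if (any(f_sample <= 0) || any(f_standard <= 0))
    stop("fluorescence values must be positive")
  standard_size_mb * f_sample / f_standard
}

#' Heterochromatin content under the fixed-euchromatin assumption
#'
#' The euchromatic portion of the genome is assumed constant across
#' karyotypes: 232 Mb (diploid) for individuals with two X chromosomes and
#' 210 Mb for individuals with a single X. Heterochromatin content is the
#' measured diploid size minus that constant.
#'
#' @param diploid_size_mb Diploid genome size in Mb.
#' @param karyotype A [karyotype_spec()].
#' @return Heterochromatin content in Mb.
#' @export
heterochromatin_content <- function(diploid_size_mb, karyotype) {
  stopifnot(inherits(karyotype, "karyotype_spec"))
  const <- euchromatin_constant(karyotype)
  if (any(diploid_size_mb < const))
    stop("diploid size below the euchromatin constant (", const,
         " Mb) implies negative heterochromatin")
  diploid_size_mb - const
}

euchromatin_constant <- function(karyotype) {
  if (karyotype$n_X >= 2) 232
  else if (karyotype$n_X == 1) 210
  else stop("euchromatin constant defined only for n_X >= 1")
}
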