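#' Heterochromatin sink model
#'
#' Generative rule for how repressive-mark density responds to total repeat
#' content: heterochromatin factors are present in limited amounts, so the
#' per-window mark density in heterochromatic blocks scales inversely with
#' the karyotype's heterochromatin content,
#' `density(k) = base * (reference_het / het(k))^exponent`, never below the
#' euchromatic background floor. Karyotypes with less repetitive DNA than the
#' reference additionally spread heterochromatin outward past the annotated
#' boundary, proportionally to their repeat deficit.
#'
#' @param reference_het_content Reference heterochromatin content in Mb
#'   (default 148, the wildtype-male value of the measured gradient).
#' @param mark_density_base Mean mark density per heterochromatic window at
#'   the reference het content.
#' @param euchromatin_floor Background mark density in euchromatin.
#' @param exponent Sink strength; 0 disables the sink (all karyotypes equal),
#'   1 (default) is strict stoichiometric dilution.
#' @param spreading_scale Maximum boundary spreading in bp per unit relative
#'   repeat deficit (default 3e5).
#' @param het_content_table Named Mb lookup per karyotype label; defaults to
#'   the measured diploid gradient X0 109 < XX 125 < XY 148 < XXY 158 <
#'   XYY 185.
#' @return Object of class `sink_model`.
#' @export
sink_model <- function(reference_het_content = 148,
                       mark_density_base = 8,
                       euchromatin_floor = 0.5,
                       exponent = 1,
                       spreading_scale = 3e5,
                       het_content_table = c(X0 = 109, XX = 125, XY = 148,
                                             XXY = 158, XYY = 185)) {
  stopifnot(reference_het_content > 0, mark_density_base > 0,
            euchromatin_floor >= 0, all(het_content_table > 0))
  structure(list(reference_het_content = reference_het_content,
                 mark_density_base = mark_density_base,
                 euchromatin_floor = euchromatin_floor,
                 exponent = exponent,
                 spreading_scale = spreading_scale,
                 het_content_table = het_content_table),
            class = "sink_model")
}

sink_het_content <- function(sink, karyotype) {
  h <- sink$het_content_table[[karyotype$label]]
  if (is.null(h)) stop("no heterochromatin content configured for karyotype ",
                       karyotype$label)
  h
}

#' Heterochromatic mark density for a karyotype under the sink rule
#' @param sink A [sink_model()].
#' @param karyotype A [karyotype_spec()].
#' @return Per-window mark density (scalar).
#' @export
sink_mark_density <- function(sink, karyotype) {
  h <- sink_het_content(sink, karyotype)
  max(sink$euchromatin_floor,
      sink$mark_density_base *
        (sink$reference_het_content / h)^sink$exponent)
}

#' Boundary spreading for a karyotype under the sink rule
#'
#' Karyotypes with less repetitive DNA than the reference concentrate the
#' limited heterochromatin machinery and spread marks past the annotated
#' boundary into normally euchromatic sequence. Returns the outward shift in
#' bp (0 for karyotypes at or above the reference repeat content; dilution,
#' not retreat, is their phenotype).
#'
#' @inheritParams sink_mark_density
#' @return Boundary shift in bp (>= 0).
#' @export
sink_boundary_shift <- function(sink, karyotype) {
  h <- sink_het_content(sink, karyotype)
  deficit <- max(0, (sink$reference_het_content - h) /
                   sink$reference_het_content)
  sink$spreading_scale * deficit * sink$exponent
}
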