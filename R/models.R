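# reference age (years) of the Watson & Yellott age correction
WY_REFERENCE_AGE <- 28.58

#' Model identifiers of the eight classical pupil light models
#'
#' Returns the identifiers accepted by [predict_diameter()]:
#' `"holladay"`, `"crawford"`, `"moon_spencer"`, `"degroot_gebhard"`,
#' `"stanley_davies"`, `"barten"`, `"blackie_howland"`, `"watson_yellott"`.
#'
#' @return Character vector of length 8.
#' @export
pupil_model_ids <- function() {
  c("holladay", "crawford", "moon_spencer", "degroot_gebhard",
    "stanley_davies", "barten", "blackie_howland", "watson_yellott")
}

#' Adaptation-field geometry
#'
#' Describes the angular extent of the adapting field and the convention used
#' to convert it to a solid-angle-like area in square degrees, as required by
#' the Stanley & Davies, Barten and Watson & Yellott models.
#'
#' @param kind `"rectangular"` or `"circular"`.
#' @param sizes Angular extents in degrees: `c(alpha_x, alpha_y)` for a
#'   rectangular field, a single diameter `D` for a circular field.
#' @param conversion Conversion rule: `"product"` (rectangle,
#'   `alpha_x * alpha_y`), `"circle_area"` (`pi/4 * D^2`), `"spherical_cap"`
#'   (exact solid-angle formula `6566*pi*(1 - cos(D*pi/360))`, recommended
#'   for fields wider than 15 degrees), or `"legacy_toolbox"`
#'   (`(D/2)*pi`, a documented pitfall of older toolboxes; warns on use).
#'   Default: `"product"` for rectangles, `"circle_area"` for circles.
#' @param allow_large_flat If `FALSE` (default) using a flat-geometry
#'   conversion for extents above 15 degrees emits a warning recommending
#'   `"spherical_cap"`.
#'
#' @return An object of class `"field_geometry"`.
#' @examples
#' field_geometry("circular", 53.13)
#' field_geometry("rectangular", c(10, 20))
#' @export
field_geometry <- function(kind = c("circular", "rectangular"), sizes,
                           conversion = NULL, allow_large_flat = FALSE) {
  kind <- match.arg(kind)
  sizes <- as.numeric(sizes)
  if (any(!is.finite(sizes)) || any(sizes <= 0) || any(sizes >= 180))
    stop("invalid field geometry: angular extents must lie in (0, 180) degrees",
         call. = FALSE)
  n_expect <- if (kind == "rectangular") 2L else 1L
  if (length(sizes) != n_expect)
    stop(sprintf("%s fields need %d angular extent(s)", kind, n_expect),
         call. = FALSE)
  if (is.null(conversion))
    conversion <- if (kind == "rectangular") "product" else "circle_area"
  conversion <- match.arg(conversion,
    c("product", "circle_area", "spherical_cap", "legacy_toolbox"))
  if (conversion == "product" && kind != "rectangular")
    stop("'product' conversion applies to rectangular fields", call. = FALSE)
  if (conversion %in% c("circle_area", "legacy_toolbox") && kind != "circular")
    stop(sprintf("'%s' conversion applies to circular fields", conversion),
         call. = FALSE)
  if (!allow_large_flat && conversion %in% c("product", "circle_area") &&
      any(sizes > 15))
    warning(paste("field extent exceeds 15 degrees; the flat-geometry",
                  "conversion overestimates the solid angle, consider",
                  "conversion = \"spherical_cap\""), call. = FALSE)
  structure(list(kind = kind, sizes = sizes, conversion = conversion),
            class = "field_geometry")
}

#' Convert a field geometry to square degrees
#'
#' Applies the conversion rule stored in a [field_geometry()] object:
#' \describe{
#'   \item{product}{\eqn{\alpha = \alpha_x \alpha_y} (Barten's rectangle rule).}
#'   \item{circle_area}{\eqn{\alpha = (\pi/4) D^2} (flat circular field).}
#'   \item{spherical_cap}{\eqn{\alpha = 6566\pi(1 - \cos(D \pi / 360))},
#'     the exact conversion recommended for fields wider than 15 degrees.
#'     Rectangular fields are first mapped to the circular-equivalent
#'     diameter \eqn{D = 2\sqrt{\alpha_x \alpha_y / \pi}}.}
#'   \item{legacy_toolbox}{\eqn{\alpha = (D/2)\pi}; only kept to reproduce a
#'     documented pitfall of older model toolboxes, warns on every use.}
#' }
#'
#' @param field A [field_geometry()] object.
#' @return Adaptation-field area in deg^2 (positive scalar).
#' @examples
#' field_to_deg2(field_geometry("rectangular", c(10, 20)))  # 200
#' field_to_deg2(field_geometry("circular", 53.13))         # ~2217
#' @export
field_to_deg2 <- function(field) {
  if (!inherits(field, "field_geometry"))
    stop("'field' must be a field_geometry object", call. = FALSE)
  s <- field$sizes
  switch(field$conversion,
    product = s[1] * s[2],
    circle_area = pi / 4 * s[1]^2,
    spherical_cap = {
      d <- if (field$kind == "circular") s[1] else 2 * sqrt(s[1] * s[2] / pi)
      6566 * pi * (1 - cos(d * pi / 360))
    },
    legacy_toolbox = {
      warning(paste("'legacy_toolbox' conversion (alpha_deg/2)*pi is a",
                    "documented approximation error; use 'circle_area' or",
                    "'spherical_cap'"), call. = FALSE)
      s[1] / 2 * pi
    })
}

#' Viewing conditions for pupil-diameter prediction
#'
#' Bundles the stimulus and observer parameters the models depend on:
#' adapting luminance, field geometry, observer age and number of exposed
#' eyes. Only the Stanley & Davies, Barten and Watson & Yellott models use
#' the field; only Watson & Yellott uses age and eyes.
#'
#' @param luminance Adapting luminance in cd/m^2 (> 0).
#' @param field Optional [field_geometry()].
#' @param age_years Optional observer age in years. Ages outside 17–83
#'   (the range of the Winn et al. data behind the age correction) warn;
#'   outside 16–90 they error.
#' @param eyes Number of exposed eyes, 1 or 2. Monocular viewing enters the
#'   Watson & Yellott model as an effective-luminance factor e = 0.1;
#'   binocular as e = 1.
#'
#' @return An object of class `"viewing_conditions"`.
#' @examples
#' viewing_conditions(100, field_geometry("circular", 53.13),
#'                    age_years = 22.2, eyes = 2)
#' @export
viewing_conditions <- function(luminance, field = NULL, age_years = NULL,
                               eyes = NULL) {
  if (!is.numeric(luminance) || length(luminance) != 1 ||
      !is.finite(luminance) || luminance <= 0)
    stop("'luminance' must be a positive scalar (cd/m^2)", call. = FALSE)
  if (!is.null(field) && !inherits(field, "field_geometry"))
    stop("'field' must be a field_geometry object", call. = FALSE)
  if (!is.null(age_years)) {
    if (!is.finite(age_years) || age_years < 16 || age_years > 90)
      stop("'age_years' outside the supported range [16, 90]", call. = FALSE)
    if (age_years < 17 || age_years > 83)
      warning("age outside 17-83, beyond the range of the age-correction data",
              call. = FALSE)
  }
  if (!is.null(eyes) && !eyes %in% c(1L, 2L))
    stop("'eyes' must be 1 or 2", call. = FALSE)
  structure(list(luminance = luminance, field = field,
                 age_years = age_years,
                 eyes = if (is.null(eyes)) NULL else as.integer(eyes)),
            class = "viewing_conditions")
}

# monocular effective-luminance factor
eye_factor <- function(eyes) if (eyes == 1L) 0.1 else 1

# Stanley & Davies functional core, shared with the Watson-Yellott base
# diameter D_SDW (which multiplies L*alpha by the eye factor e)
stanley_davies_core <- function(l_alpha) {
  z <- (l_alpha / 846)^0.41
  7.75 - 5.75 * z / (z + 2)
}

#' Predict pupil diameter with a classical model
#'
#' Evaluates one of the eight closed-form luminance-based pupil diameter
#' models. All formulas are carried at full printed coefficient precision;
#' rounding is left to presentation.
#'
#' \describe{
#'   \item{holladay}{\eqn{D = 7 \exp(-0.1007 L^{0.4})}}
#'   \item{crawford}{\eqn{D = 5 - 2.2 \tanh(0.61151 + 0.447 \log_{10} L)}}
#'   \item{moon_spencer}{\eqn{D = 4.9 - 3 \tanh(0.4 \log_{10} L)}}
#'   \item{degroot_gebhard}{\eqn{D = 7.175 \exp(-0.00092 (7.597 + \log_{10} L)^3)}}
#'   \item{stanley_davies}{\eqn{D = 7.75 - 5.75 \frac{(L\alpha/846)^{0.41}}
#'     {(L\alpha/846)^{0.41} + 2}}}
#'   \item{barten}{\eqn{D = 5 - 3 \tanh(0.4 \log_{10} (L\alpha/40^2))}}
#'   \item{blackie_howland}{\eqn{D = 5.697 - 0.658 \log_{10} L +
#'     0.07 (\log_{10} L)^2} (fit to data up to 10 cd/m^2; warns above)}
#'   \item{watson_yellott}{the unified formula: the Stanley & Davies form
#'     with the monocular factor e on \eqn{L\alpha} gives the base diameter
#'     \eqn{D_{SDW}}, then the age correction
#'     \eqn{D = D_{SDW} + (y - y_0)(0.02132 - 0.009562 D_{SDW})} with
#'     reference age \eqn{y_0 = 28.58} years.}
#' }
#'
#' @param model_id One of [pupil_model_ids()].
#' @param cond A [viewing_conditions()] object, or a bare luminance for
#'   models that need nothing else.
#' @return A list of class `"model_prediction"` with elements `model_id`,
#'   `diameter_mm` and, for Watson & Yellott, `intermediate_dsdw_mm`.
#' @examples
#' predict_diameter("crawford", 100)            # 3.007 mm
#' predict_diameter("watson_yellott",
#'   viewing_conditions(100, field_geometry("circular", 53.13),
#'                      age_years = 22.2, eyes = 2))  # 3.019 mm
#' @export
predict_diameter <- function(model_id, cond) {
  model_id <- match.arg(model_id, pupil_model_ids())
  if (is.numeric(cond)) cond <- viewing_conditions(cond)
  if (!inherits(cond, "viewing_conditions"))
    stop("'cond' must be a viewing_conditions object or a luminance",
         call. = FALSE)
  L <- cond$luminance

  needs_field <- model_id %in% c("stanley_davies", "barten", "watson_yellott")
  if (needs_field && is.null(cond$field))
    stop(sprintf("model '%s' requires a field geometry (missing parameter)",
                 model_id), call. = FALSE)
  if (model_id == "watson_yellott" &&
      (is.null(cond$age_years) || is.null(cond$eyes)))
    stop("watson_yellott requires 'age_years' and 'eyes' (missing parameter)",
         call. = FALSE)
  alpha <- if (needs_field) field_to_deg2(cond$field) else NULL

  dsdw <- NULL
  d <- switch(model_id,
    holladay = 7 * exp(-0.1007 * L^0.4),
    crawford = 5 - 2.2 * tanh(0.61151 + 0.447 * log10(L)),
    moon_spencer = 4.9 - 3 * tanh(0.4 * log10(L)),
    degroot_gebhard = 7.175 * exp(-0.00092 * (7.597 + log10(L))^3),
    stanley_davies = stanley_davies_core(L * alpha),
    barten = 5 - 3 * tanh(0.4 * log10(L * alpha / 40^2)),
    blackie_howland = {
      if (L > 10)
        warning("blackie_howland fitted on data up to 10 cd/m^2 only",
                call. = FALSE)
      5.697 - 0.658 * log10(L) + 0.07 * log10(L)^2
    },
    watson_yellott = {
      dsdw <- stanley_davies_core(L * alpha * eye_factor(cond$eyes))
      dsdw + (cond$age_years - WY_REFERENCE_AGE) *
        (0.02132 - 0.009562 * dsdw)
    })

  structure(list(model_id = model_id, diameter_mm = d,
                 intermediate_dsdw_mm = dsdw),
            class = "model_prediction")
}

#' @export
print.model_prediction <- function(x, ...) {
  cat(sprintf("%s: %.3f mm\n", x$model_id, x$diameter_mm))
  if (!is.null(x$intermediate_dsdw_mm))
    cat(sprintf("  (base diameter D_SDW: %.3f mm)\n", x$intermediate_dsdw_mm))
  invisible(x)
}

#' Benchmark default adaptation field
#'
#' The 700 x 700 mm adapting surface viewed at 700 mm corresponds to a
#' visual angle of 2*atan(0.5) = 53.13 degrees. For model evaluation it is
#' represented as a circular-equivalent field of that diameter converted
#' with the flat circle-area rule, the convention under which the unified
#' formula reproduces the published worked examples.
#'
#' @return A [field_geometry()] object.
#' @export
benchmark_field <- function() {
  field_geometry("circular", 2 * atan(0.5) * 180 / pi,
                 conversion = "circle_area", allow_large_flat = TRUE)
}
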