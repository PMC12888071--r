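## Deterministic survey-design calculators: potential survey area, campaign
## economic cost, post-processing time. Shipped defaults are the field
## campaign's own figures (Sulawesi Selatan, 2025 USD).

#' Detection-geometry configuration
#'
#' @param pt_radius_m audible-detection radius of a point-transect sampling
#'   point (m); default 130, the maximum distance the loud call carries.
#' @param pt_points sampling points per transect (default 5).
#' @param pam_radius_m omnidirectional recorder detection radius (m).
#' @param ct_radius_m camera detection distance (m); default 23 per the
#'   manufacturer.
#' @param ct_angle_deg camera field-of-view angle (degrees); default 35.
#' @return Named list ("GeometryConfig").
#' @export
geometryConfig <- function(pt_radius_m = 130, pt_points = 5,
                           pam_radius_m = 130, ct_radius_m = 23,
                           ct_angle_deg = 35) {
  cfg <- list(pt_radius_m = pt_radius_m, pt_points = pt_points,
              pam_radius_m = pam_radius_m, ct_radius_m = ct_radius_m,
              ct_angle_deg = ct_angle_deg)
  if (any(unlist(cfg[c(1, 3, 4)]) <= 0))
    stop("radii must be positive", call. = FALSE)
  if (ct_angle_deg <= 0 || ct_angle_deg > 360)
    stop("ct_angle_deg must lie in (0, 360]", call. = FALSE)
  cfg
}

#' Campaign cost components
#'
#' Per-person per-day components in USD plus device/battery costs. The
#' defaults: 5 food, 15 lodging, 20 transport, 10 full-day assistant salary
#' (5 for the half-day sensor deployment visits); 3 field days for point
#' transects, 2 for sensor deploy/retrieve; 100 USD per device; batteries
#' 10 USD (camera) / 5 USD (recorder).
#'
#' @param food,lodging,transport,assistant_salary_full,assistant_salary_half
#'   daily components (USD).
#' @param field_days_pt,field_days_sensor field days per campaign.
#' @param device_cost_ct,device_cost_pam,battery_cost_ct,battery_cost_pam
#'   one-off equipment costs (USD).
#' @return Named list ("CostConfig").
#' @export
costConfig <- function(food = 5, lodging = 15, transport = 20,
                       assistant_salary_full = 10,
                       assistant_salary_half = 5,
                       field_days_pt = 3, field_days_sensor = 2,
                       device_cost_ct = 100, device_cost_pam = 100,
                       battery_cost_ct = 10, battery_cost_pam = 5) {
  cfg <- list(food = food, lodging = lodging, transport = transport,
              assistant_salary_full = assistant_salary_full,
              assistant_salary_half = assistant_salary_half,
              field_days_pt = field_days_pt,
              field_days_sensor = field_days_sensor,
              device_cost_ct = device_cost_ct,
              device_cost_pam = device_cost_pam,
              battery_cost_ct = battery_cost_ct,
              battery_cost_pam = battery_cost_pam)
  if (any(unlist(cfg) < 0))
    stop("cost components must be non-negative", call. = FALSE)
  cfg
}

#' Post-processing time configuration
#'
#' Hours to turn one site-campaign of raw data into confirmed detections,
#' by method and processing mode (manual annotation vs supervised automatic
#' detection). Point transects have a manual mode only (field-note
#' transcription).
#'
#' @param pt_manual,ct_manual,ct_automatic,pam_manual,pam_automatic hours.
#' @return Named list ("PostProcessingConfig").
#' @export
postProcessingConfig <- function(pt_manual = 1, ct_manual = 8,
                                 ct_automatic = 3, pam_manual = 40,
                                 pam_automatic = 16) {
  if (ct_automatic > ct_manual || pam_automatic > pam_manual)
    stop("automatic processing cannot take longer than manual",
         call. = FALSE)
  list(PT = c(manual = pt_manual),
       CT = c(manual = ct_manual, automatic = ct_automatic),
       PAM = c(manual = pam_manual, automatic = pam_automatic))
}

#' Potential survey area per method
#'
#' The ground area one survey can cover, from each method's detection
#' geometry: a point transect covers \code{pt_points} full circles of the
#' audible radius, a recorder one full circle, a camera a circular sector
#' of its view angle. Returned in hectares, unrounded (round only at
#' reporting).
#'
#' @param method "PT", "CT" or "PAM".
#' @param geometry a \code{\link{geometryConfig}}.
#' @return Area in hectares.
#' @examples
#' round(surveyArea("PT"), 2)   # 26.55
#' round(surveyArea("PAM"), 2)  # 5.31
#' @export
surveyArea <- function(method, geometry = geometryConfig()) {
  m2 <- switch(method,
    PT = geometry$pt_points * pi * geometry$pt_radius_m^2,
    PAM = pi * geometry$pam_radius_m^2,
    CT = (geometry$ct_angle_deg / 360) * pi * geometry$ct_radius_m^2,
    stop("unknown method '", method, "'", call. = FALSE))
  m2 / 1e4
}

#' Campaign cost per survey site
#'
#' Point transects: field days times the full daily rate. Sensors: field
#' days times the reduced daily rate (half-day salary) plus one device and
#' its batteries.
#'
#' @param method "PT", "CT" or "PAM".
#' @param cost a \code{\link{costConfig}}.
#' @return Cost in USD.
#' @examples
#' surveyCost("PT")  # 150
#' surveyCost("CT")  # 200
#' @export
surveyCost <- function(method, cost = costConfig()) {
  dailyFull <- cost$food + cost$lodging + cost$transport +
    cost$assistant_salary_full
  dailyHalf <- cost$food + cost$lodging + cost$transport +
    cost$assistant_salary_half
  switch(method,
    PT = cost$field_days_pt * dailyFull,
    CT = cost$field_days_sensor * dailyHalf + cost$device_cost_ct +
      cost$battery_cost_ct,
    PAM = cost$field_days_sensor * dailyHalf + cost$device_cost_pam +
      cost$battery_cost_pam,
    stop("unknown method '", method, "'", call. = FALSE))
}

#' Post-processing hours per method and mode
#'
#' @param method "PT", "CT" or "PAM".
#' @param mode "manual" or "automatic" (point transects: manual only).
#' @param config a \code{\link{postProcessingConfig}}.
#' @return Hours.
#' @export
postProcessingHours <- function(method, mode = c("manual", "automatic"),
                                config = postProcessingConfig()) {
  mode <- match.arg(mode)
  if (!method %in% names(config))
    stop("unknown method '", method, "'", call. = FALSE)
  h <- config[[method]]
  if (!mode %in% names(h))
    stop("mode '", mode, "' is undefined for method ", method,
         call. = FALSE)
  unname(h[mode])
}

#' Survey-design summary table
#'
#' One row per method: survey time per occasion, potential survey area
#' (2 d.p.), campaign cost, and manual (automatic) post-processing hours.
#'
#' @param geometry,cost,postprocessing configuration lists.
#' @return data.frame with rows PT, CT, PAM.
#' @export
designSummary <- function(geometry = geometryConfig(),
                          cost = costConfig(),
                          postprocessing = postProcessingConfig()) {
  methods <- c("PT", "CT", "PAM")
  data.frame(
    method = methods,
    survey_time_hours = c(5 / 3, 120, 120),
    survey_area_ha = round(vapply(methods, surveyArea, 0,
                                  geometry = geometry), 2),
    cost_usd = vapply(methods, surveyCost, 0, cost = cost),
    postprocessing_manual_h = vapply(methods, postProcessingHours, 0,
                                     mode = "manual",
                                     config = postprocessing),
    postprocessing_automatic_h = c(NA,
      postProcessingHours("CT", "automatic", postprocessing),
      postProcessingHours("PAM", "automatic", postprocessing)),
    row.names = NULL)
}
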