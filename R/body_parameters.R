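#' @keywords internal
"_PACKAGE"

# Canonical segment order: head, chest, abdomen, then paired limbs
# (left before right): upper arms, forearms, hands, thighs, calves, feet.
.segment_types <- c("head", "chest", "abdomen", "upper_arm", "forearm",
                    "hand", "thigh", "calf", "foot")

.segment_names <- c("head", "chest", "abdomen",
                    "upper_arm_l", "upper_arm_r",
                    "forearm_l", "forearm_r",
                    "hand_l", "hand_r",
                    "thigh_l", "thigh_r",
                    "calf_l", "calf_r",
                    "foot_l", "foot_r")

.sector_names <- c("anterior", "exterior", "posterior", "inferior")

#' Per-type passive parameter table
#'
#' One row per segment type (paired limbs share a row). Columns: surface
#' area `A` (m^2), basal core metabolic rate `M_cr` (W), skin metabolic
#' rate `M_sk` (W), heat capacitances `C_cr`, `C_bl_a`, `C_bl_v`, `C_sk`
#' (J/K), total core-to-skin conductance `K_cr_sk` (W/K), and basal /
#' minimal / maximal skin blood flow (cm^3/h). Geometry columns (`L_n`
#' segment length m, `z_c` mid-height above floor m) carry canonical
#' anthropometric values for a standing standard body; the skin-layer
#' radius is derived as `r = A / (2 pi L_n)` for a cylindrical shell.
#'
#' @return data.frame with one row per segment type.
#' @export
segment_table <- function() {
  d <- data.frame(
    type  = .segment_types,
    A     = c(0.140, 0.336, 0.221, 0.096, 0.063, 0.050, 0.209, 0.112, 0.056),
    M_cr  = c(18.433, 5.95, 46.86, 1.062, 0.593, 0.095, 1.708, 0.754, 0.146),
    M_sk  = c(0.219, 0.6, 0.6, 0.182, 0.101, 0.093, 0.343, 0.153, 0.127),
    C_cr  = c(12247.1, 36732.1, 67160.5, 6707.9, 3750.1, 791.4,
              11926.3, 5262.3, 1465.3),
    C_bl_a = c(810.5, 2266.8, 566.7, 49.6, 32.3, 21.4, 93.1, 36.8, 18.7),
    C_bl_v = c(2482.1, 6941.9, 1735.5, 151.9, 99.1, 65.7, 285.1, 112.6, 57.2),
    C_sk  = c(1710.2, 13624.8, 13624.8, 1284.02, 717.9, 723.5,
              4133.9, 1850.8, 1347.4),
    K_cr_sk = c(1.848, 4.921, 4.921, 1.304, 0.913, 0.545, 1.564, 1.216, 0.631),
    m_sk_basal = c(6050, 3441.5, 2272.5, 910, 508, 1114, 1456, 651, 934),
    m_sk_min = c(4518, 0, 0, 0, 0, 627, 0, 0, 301),
    m_sk_max = c(16552, 33246, 21953, 8319, 5553, 4454, 12453, 8253, 5278),
    L_n   = c(0.22, 0.30, 0.25, 0.30, 0.27, 0.18, 0.40, 0.38, 0.24),
    z_c   = c(1.60, 1.33, 1.05, 1.28, 1.00, 0.78, 0.70, 0.30, 0.05),
    stringsAsFactors = FALSE
  )
  d$r <- signif(d$A / (2 * pi * d$L_n), 6)
  d$th_sk <- 0.001              # skin shell thickness, m
  d$K_sk <- 0.47                # skin thermal conductivity, W/(m K)
  d$epsilon <- 0.95             # skin / clothing long-wave emissivity
  d$W_cr <- 0                   # mechanical work, W (resting subjects)
  d
}

#' Set-point and distribution-coefficient table
#'
#' Per segment type: skin set-point temperature `T_sk0` (degrees C), skin
#' sensitivity weight `alpha_sk`, shivering coefficient `alpha_sh` and
#' sweating coefficient `alpha_sw`. Paired-limb rows hold the per-side
#' value, so summing the coefficients over all fifteen segments (paired
#' rows counted twice) gives approximately 1.
#'
#' @return data.frame with one row per segment type.
#' @export
thermoreg_table <- function() {
  data.frame(
    type = .segment_types,
    T_sk0 = c(35.6, 33.6, 33.3, 33.4, 34.6, 35.2, 33.8, 33.4, 33.9),
    alpha_sk = c(0.07, 0.281, 0.212, 0.023, 0.012, 0.092, 0.05, 0.025, 0.017),
    alpha_sh = c(0.02, 0.485, 0.365, 0.004, 0.026, 0, 0.023, 0.012, 0),
    alpha_sw = c(0.081, 0.275, 0.206, 0.051, 0.026, 0.016, 0.073, 0.036, 0.018),
    stringsAsFactors = FALSE
  )
}

# map the 15 per-side segments onto the 9 type rows
.type_index <- function() {
  match(sub("_(l|r)$", "", .segment_names), .segment_types)
}

#' Default whole-body parameter set
#'
#' Builds the standard 15-segment body: the per-type passive table is
#' replicated onto both sides for paired limbs, and the thermoregulatory
#' set points, distribution coefficients and controller constants are
#' attached. The result is the single standard body used by all scenario
#' fixtures; any field may be overridden via [read_body_config()] or by
#' editing the returned object.
#'
#' @param overrides optional named list, `list(segment = list(field = value))`,
#'   applied to the per-side segment table. Unknown segment or field names
#'   are an error.
#' @return object of class `bioheat_body`: a list with `segments` (15-row
#'   data.frame) and `thermo` (controller parameter list).
#' @export
default_body <- function(overrides = NULL) {
  tab <- segment_table()
  idx <- .type_index()
  seg <- tab[idx, , drop = FALSE]
  seg$name <- .segment_names
  rownames(seg) <- seg$name
  seg <- seg[, c("name", setdiff(names(seg), c("name", "type")))]

  th <- thermoreg_table()[idx, , drop = FALSE]
  thermo <- list(
    T_sk0 = th$T_sk0,
    alpha_sk = th$alpha_sk,
    alpha_sh = th$alpha_sh,
    alpha_sw = th$alpha_sw,
    T_cr_set = 36.9,          # head thermal reference core temperature, C
    T_head_set_sweat = 37,    # sweating set point, C
    c_bl = 4000,              # blood specific heat, J/(kg K)
    rho_bl = 1059,            # blood density, kg/m^3
    body_mass_ref = 74.30,    # dehydration denominator, kg
    lambda_sweat = 2430e3,    # latent heat of sweat evaporation, J/kg
    co_core = 277000,         # total basal core perfusion, cm^3/h
    kappa_vessel = 0.01,      # core-vessel conductance per unit C_bl, W/K/(J/K)
    gains = list(
      dil_cr = 117000,        # central vasodilation drive, cm^3/h per K
      dil_sk = 7500,          # peripheral vasodilation drive, cm^3/h per K
      con_cr = 20,            # central vasoconstriction drive, 1/K
      con_sk = 0.5,           # peripheral vasoconstriction drive, 1/K
      sh = 19.4               # shivering gain, W/K^2
    )
  )
  body <- structure(list(segments = seg, thermo = thermo),
                    class = "bioheat_body")
  if (!is.null(overrides)) body <- .apply_body_overrides(body, overrides)
  body
}

.apply_body_overrides <- function(body, overrides) {
  stopifnot(is.list(overrides))
  for (nm in names(overrides)) {
    if (!nm %in% body$segments$name)
      stop("unknown segment in body overrides: ", nm)
    fields <- overrides[[nm]]
    for (f in names(fields)) {
      if (!f %in% names(body$segments))
        stop("unknown field in body overrides: ", nm, "$", f)
      body$segments[body$segments$name == nm, f] <- fields[[f]]
    }
  }
  body
}

#' Validate a body parameter set
#'
#' Checks the physical and physiological invariants of the passive and
#' thermoregulatory parameter sets: strictly positive capacitances, areas
#' and lengths; `m_sk_min <= m_sk_basal <= m_sk_max` per segment; skin set
#' points within 30-37 degrees C; and distribution-coefficient sums within
#' 0.99-1.01 over the fifteen segments.
#'
#' @param body a `bioheat_body`.
#' @param strict if `TRUE` (default), any violation raises an error;
#'   otherwise the report is returned for inspection.
#' @return data.frame of violations (zero rows when valid), invisibly when
#'   `strict = TRUE`.
#' @export
validate_body <- function(body, strict = TRUE) {
  seg <- body$segments
  th <- body$thermo
  v <- list()
  add <- function(segment, field, message)
    v[[length(v) + 1]] <<- data.frame(segment = segment, field = field,
                                      message = message,
                                      stringsAsFactors = FALSE)
  pos_fields <- c("A", "C_cr", "C_bl_a", "C_bl_v", "C_sk", "L_n", "r",
                  "th_sk", "K_sk", "K_cr_sk")
  for (f in pos_fields) {
    bad <- which(!(seg[[f]] > 0))
    for (i in bad) add(seg$name[i], f, sprintf("%s must be positive", f))
  }
  bad <- which(!(seg$m_sk_min <= seg$m_sk_basal & seg$m_sk_basal <= seg$m_sk_max))
  for (i in bad) add(seg$name[i], "m_sk_basal",
                     "requires m_sk_min <= m_sk_basal <= m_sk_max")
  for (a in c("alpha_sk", "alpha_sh", "alpha_sw")) {
    s <- sum(th[[a]])
    if (s < 0.99 || s > 1.01)
      add("(all)", a, sprintf("%s sums to %.4f, outside [0.99, 1.01]", a, s))
  }
  bad <- which(th$T_sk0 < 30 | th$T_sk0 > 37)
  for (i in bad) add(seg$name[i], "T_sk0", "set point outside [30, 37] C")
  rep <- if (length(v)) do.call(rbind, v) else
    data.frame(segment = character(), field = character(),
               message = character(), stringsAsFactors = FALSE)
  if (strict && nrow(rep) > 0)
    stop("invalid body parameters:\n",
         paste(sprintf("  %s/%s: %s", rep$segment, rep$field, rep$message),
               collapse = "\n"))
  if (strict) invisible(rep) else rep
}

#' Write / read a body parameter set as JSON
#'
#' The configuration is keyed by segment name and field; reloading
#' reproduces every numeric field bit-exactly. Thermoregulatory constants
#' are stored under a `thermo` key.
#'
#' @param body a `bioheat_body`.
#' @param path file path.
#' @return `read_body_config` returns a `bioheat_body`.
#' @export
write_body_config <- function(body, path) {
  seg <- body$segments
  seg_list <- lapply(seq_len(nrow(seg)), function(i)
    as.list(seg[i, setdiff(names(seg), "name")]))
  names(seg_list) <- seg$name
  jsonlite::write_json(list(segments = seg_list, thermo = body$thermo),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_body_config
#' @export
read_body_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_body()
  known <- setdiff(names(base$segments), "name")
  seg_names <- names(cfg$segments)
  if (!setequal(seg_names, .segment_names))
    stop("body config must define exactly the 15 canonical segments")
  for (nm in .segment_names) {
    fields <- cfg$segments[[nm]]
    extra <- setdiff(names(fields), known)
    if (length(extra))
      stop("unknown field(s) in body config for ", nm, ": ",
           paste(extra, collapse = ", "))
    for (f in names(fields))
      base$segments[base$segments$name == nm, f] <- as.numeric(fields[[f]])
  }
  if (!is.null(cfg$thermo)) {
    extra <- setdiff(names(cfg$thermo), names(base$thermo))
    if (length(extra))
      stop("unknown thermo field(s): ", paste(extra, collapse = ", "))
    num <- function(x) if (is.numeric(x)) as.numeric(x) else x
    for (f in names(cfg$thermo)) {
      if (f == "gains") {
        for (gn in names(cfg$thermo$gains))
          base$thermo$gains[[gn]] <- num(cfg$thermo$gains[[gn]])
      } else base$thermo[[f]] <- num(cfg$thermo[[f]])
    }
  }
  base
}

#' Segment and sector naming helpers
#'
#' @return character vectors of the canonical 15 segment names and the
#'   four angular sector names.
#' @export
segment_names <- function() .segment_names

#' @rdname segment_names
#' @export
sector_names <- function() .sector_names
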