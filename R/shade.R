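# Neighbour-detection signals (virtual leaf touching, low R:FR at the
# lamina tip) and the hyponasty / petiole-elongation response rules.

#' Detect virtual leaf touching
#'
#' A leaf is touched when its lamina comes within `tolerance` of a lamina
#' of another plant in 3D (a symmetric relation). Contact between leaves of
#' the same plant counts only when `self` is `TRUE`.
#'
#' @param scene a `canopy_scene`.
#' @param tolerance contact distance, meters (default 2 mm).
#' @param self include same-plant contact?
#' @return data.frame (plant, leaf, touched).
#' @export
detect_touch <- function(scene, tolerance = 0.002, self = FALSE) {
  prim <- scene_primitives(scene)
  if (nrow(prim$lam) == 0)
    return(data.frame(plant = integer(0), leaf = integer(0),
                      touched = logical(0)))
  touched <- cpp_touch(prim$lam, tolerance, 24L, self)
  data.frame(plant = prim$lam[, 12], leaf = prim$lam[, 13],
             touched = touched)
}

#' Evaluate neighbour-detection signals
#'
#' A leaf's response is triggered by virtual touching OR by a lamina-tip
#' R:FR strictly below the phenotype's threshold — no other pathway.
#' Phenotypes with touch disabled use only the R:FR signal.
#'
#' @param scene a `canopy_scene`.
#' @param radiation a `radiation_result` for this time step.
#' @param sas_lookup function(plant_id) returning that plant's
#'   [sas_params()]; a single `sas_params` applies to every plant.
#' @param tolerance touch tolerance, m.
#' @return data.frame (plant, leaf, touched, tip_r_fr, triggered), class
#'   `signal_state`.
#' @export
evaluate_signals <- function(scene, radiation, sas_lookup,
                             tolerance = 0.002) {
  if (inherits(sas_lookup, "sas_params")) {
    sp <- sas_lookup
    sas_lookup <- function(id) sp
  }
  tips <- radiation$tips
  if (nrow(tips) == 0)
    return(structure(data.frame(plant = integer(0), leaf = integer(0),
                                touched = logical(0), tip_r_fr = numeric(0),
                                triggered = logical(0)),
                     class = c("signal_state", "data.frame")))
  any_self <- any(vapply(unique(tips$plant),
                         function(id) isTRUE(sas_lookup(id)$self_touch),
                         logical(1)))
  tt <- detect_touch(scene, tolerance, self = any_self)
  key <- paste(tips$plant, tips$leaf)
  touched <- tt$touched[match(key, paste(tt$plant, tt$leaf))]
  touched[is.na(touched)] <- FALSE
  thr <- vapply(tips$plant, function(id) sas_lookup(id)$r_fr_threshold, 0)
  ten <- vapply(tips$plant, function(id) isTRUE(sas_lookup(id)$touch_enabled),
                logical(1))
  triggered <- (touched & ten) | (tips$r_fr < thr)
  structure(data.frame(plant = tips$plant, leaf = tips$leaf,
                       touched = touched, tip_r_fr = tips$r_fr,
                       triggered = triggered),
            class = c("signal_state", "data.frame"))
}

#' Hyponasty update rule
#'
#' On a triggered day the petiole angle steps up by the phenotype's
#' hyponasty rate, capped at the maximum angle; otherwise it is unchanged.
#' The angle never decreases (no relaxation).
#'
#' @param angle current petiole elevation(s), degrees.
#' @param triggered logical, recycled against `angle`.
#' @param sas an [sas_params()].
#' @return new angle(s), degrees.
#' @export
update_hyponasty <- function(angle, triggered, sas) {
  stopifnot(all(angle >= 0), all(angle <= sas$max_angle + 1e-9))
  ifelse(rep_len(triggered, length(angle)),
         pmin(angle + sas$hyponasty_rate, sas$max_angle), angle)
}

#' Petiole elongation multiplier
#'
#' Returns `1 + elongation_multiplier` for triggered leaves and 1
#' otherwise. Weak-SAS phenotypes carry a reduced multiplier, giving slower
#' petiole elongation than canopy or strong-SAS plants under identical
#' signals.
#'
#' @param triggered logical vector.
#' @param sas an [sas_params()].
#' @return numeric multiplier(s) >= 1.
#' @export
elongation_signal <- function(triggered, sas) {
  ifelse(triggered, 1 + sas$elongation_multiplier, 1)
}
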