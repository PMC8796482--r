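# 27-class motion taxonomy: every combination of an elbow state
# (flexion F / extension E / none), a hand state (open O / close C / none)
# and a wrist state (supination S / pronation P / none). The all-none
# combination is the explicit "no motion" class NM.

.JOINTS <- c("elbow", "wrist", "hand")

.ELBOW_LETTERS <- c(flexion = "F", extension = "E")
.HAND_LETTERS <- c(open = "O", close = "C")
.WRIST_LETTERS <- c(supination = "S", pronation = "P")

# canonical ordering: 6 discrete, 12 two-DoF, 8 three-DoF, then NM
.MOTION_CODES <- c(
  "F", "E", "C", "O", "S", "P",
  "FO", "FC", "FS", "FP", "EO", "EC", "ES", "EP",
  "CS", "CP", "OS", "OP",
  "FOS", "FOP", "FCS", "FCP", "EOS", "EOP", "ECS", "ECP",
  "NM"
)

.parse_code <- function(code) {
  if (code == "NM") {
    return(c(elbow = "none", hand = "none", wrist = "none"))
  }
  letters <- strsplit(code, "")[[1]]
  elbow <- names(.ELBOW_LETTERS)[match(intersect(letters, .ELBOW_LETTERS), .ELBOW_LETTERS)]
  hand <- names(.HAND_LETTERS)[match(intersect(letters, .HAND_LETTERS), .HAND_LETTERS)]
  wrist <- names(.WRIST_LETTERS)[match(intersect(letters, .WRIST_LETTERS), .WRIST_LETTERS)]
  c(
    elbow = if (length(elbow)) elbow else "none",
    hand = if (length(hand)) hand else "none",
    wrist = if (length(wrist)) wrist else "none"
  )
}

#' The 27-class motion taxonomy
#'
#' Every motion class decomposes into one state per joint: elbow
#' (flexion/extension/none), hand (open/close/none) and wrist
#' (supination/pronation/none). Codes concatenate the single-letter
#' primitives in elbow-hand-wrist order (e.g. `"FCS"` = elbow flexion with
#' hand close and wrist supination); the all-none combination is `"NM"`
#' (no motion). The taxonomy holds 6 discrete (1-DoF), 12 two-DoF and
#' 8 three-DoF classes plus NM.
#'
#' @return A tibble with one row per class and columns `code`, `elbow`,
#'   `hand`, `wrist` (state strings) and `dof` (number of active joints).
#' @examples
#' motion_classes()
#' @export
motion_classes <- function() {
  states <- t(vapply(.MOTION_CODES, .parse_code, character(3)))
  tibble::tibble(
    code = .MOTION_CODES,
    elbow = unname(states[, "elbow"]),
    hand = unname(states[, "hand"]),
    wrist = unname(states[, "wrist"]),
    dof = rowSums(states != "none")
  )
}

.check_codes <- function(codes) {
  bad <- setdiff(unique(codes), .MOTION_CODES)
  if (length(bad)) {
    abort(paste0(
      "Unknown motion class code(s): ", paste(bad, collapse = ", "),
      ". Valid codes are the 27-class taxonomy (see motion_classes())."
    ))
  }
  invisible(codes)
}

#' Remap motion classes to a joint classifier's output classes
#'
#' Each joint classifier discriminates three output classes: Class 1 and
#' Class 2 are the joint's two active states (elbow flexion/extension, wrist
#' supination/pronation, hand open/close) and Class 3 collects all "other
#' motions" that leave the joint idle. Over the full taxonomy each output
#' class covers exactly 9 motion classes.
#'
#' @param codes Character vector of motion class codes.
#' @param joint One of `"elbow"`, `"wrist"`, `"hand"`.
#' @return Integer vector of output classes in `1:3`.
#' @examples
#' remap_label(c("FCS", "NM", "P"), "wrist")
#' @export
remap_label <- function(codes, joint = c("elbow", "wrist", "hand")) {
  joint <- match.arg(joint)
  .check_codes(codes)
  tax <- motion_classes()
  state <- tax[[joint]][match(codes, tax$code)]
  first <- switch(joint, elbow = "flexion", wrist = "supination", hand = "open")
  second <- switch(joint, elbow = "extension", wrist = "pronation", hand = "close")
  out <- ifelse(state == first, 1L, ifelse(state == second, 2L, 3L))
  as.integer(out)
}

#' Fuse the three joint-classifier outputs into a motion class
#'
#' The parallel strategy's final decision: the triple of per-joint output
#' classes maps bijectively onto the 27-class taxonomy (Class 3 on a joint
#' means that joint is idle; all three idle gives `"NM"`). The number of
#' active DoFs of the fused class equals the number of non-Class-3 inputs.
#'
#' @param elbow,wrist,hand Integer vectors (recycled to common length) with
#'   values in `1:3`.
#' @return Character vector of motion class codes.
#' @examples
#' fuse_outputs(1, 3, 3) # "F"
#' fuse_outputs(2, 1, 1) # "EOS"
#' @export
fuse_outputs <- function(elbow, wrist, hand) {
  n <- max(length(elbow), length(wrist), length(hand))
  elbow <- rep_len(as.integer(elbow), n)
  wrist <- rep_len(as.integer(wrist), n)
  hand <- rep_len(as.integer(hand), n)
  ok <- function(x) all(!is.na(x) & x %in% 1:3)
  if (!ok(elbow) || !ok(wrist) || !ok(hand)) {
    abort("Joint outputs must be integers in 1:3.")
  }
  code <- paste0(
    c("F", "E", "")[elbow],
    c("O", "C", "")[hand],
    c("S", "P", "")[wrist]
  )
  code[code == ""] <- "NM"
  code
}
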