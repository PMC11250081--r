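# Canonical landmark and keyboard indexing, shared by every module.

# MediaPipe hand-landmark order: 0 = wrist, then four joints per digit
# (CMC/MCP, MCP/PIP, IP/DIP, tip) from thumb to little finger.
.landmark_names <- c(
  "wrist",
  "thumb_cmc", "thumb_mcp", "thumb_ip", "thumb_tip",
  "index_mcp", "index_pip", "index_dip", "index_tip",
  "middle_mcp", "middle_pip", "middle_dip", "middle_tip",
  "ring_mcp", "ring_pip", "ring_dip", "ring_tip",
  "little_mcp", "little_pip", "little_dip", "little_tip"
)

.finger_names <- c("thumb", "index", "middle", "ring", "little")

# landmark ids (0-based) of the four-joint chain of each digit
.finger_chain <- list(
  thumb  = 1:4,
  index  = 5:8,
  middle = 9:12,
  ring   = 13:16,
  little = 17:20
)

#' Canonical hand-landmark table
#'
#' The fixed 21-landmark indexing used across the package: id 0 is the
#' wrist, ids 1-4 the thumb chain, 5-8 index, 9-12 middle, 13-16 ring and
#' 17-20 the little finger, matching MediaPipe hand-pose output order.
#'
#' @return A tibble with columns `landmark_id` (0-20), `name`, `finger`
#'   (`"wrist"` or one of thumb/index/middle/ring/little) and `joint`
#'   (`"wrist"`, `"mcp"`, `"pip"`, `"dip"`, `"tip"`; the thumb chain is
#'   labelled with the same four levels for uniformity).
#' @export
#' @examples
#' hand_landmarks()
hand_landmarks <- function() {
  finger <- c("wrist", rep(.finger_names, each = 4L))
  joint <- c("wrist", rep(c("mcp", "pip", "dip", "tip"), times = 5L))
  tibble::tibble(
    landmark_id = 0:20,
    name = .landmark_names,
    finger = finger,
    joint = joint
  )
}

#' Piano key indexing helpers
#'
#' Keys are indexed 0-87 from A0 (lowest) to C8 (highest); middle C (C4)
#' is index 39.  `key_to_x()` maps a key index to the normalized image
#' x-coordinate of its centre under the overhead-camera geometry the
#' package assumes (the full keyboard spans the image width).
#'
#' @param key integer key index in 0..87.
#' @return `key_to_x()`: numeric in (0, 1).
#' @export
#' @examples
#' key_to_x(39) # middle C sits near the image centre
key_to_x <- function(key) {
  stopifnot(all(key >= 0), all(key <= 87))
  (key + 0.5) / 88
}

# index of middle C, kept as a named constant for readability
.middle_c <- 39L
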