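# Architecture specification: an explicit layer table for the U-Net /
# ConvNeXt encoder-decoder, built from a channel plan. The 43 tunable
# convolution slots are consumed in plan order:
#   encoder (31): stride-4 7x7 patchify stem | stage1: 1 block | ds |
#     stage2: 2 blocks | ds | stage3: 2 blocks | ds | stage4: 6 blocks |
#     ds | stage5: 2 blocks      (resolutions 1/4 down to 1/64)
#   decoder (12): 4 levels x (bilinear x2 up, skip concat, pw_reduce,
#     block expand, block project) back to 1/4 resolution, then a 1x1
#     classification head whose logits are bilinearly upsampled x4 to full
#     resolution (head and upsampling are not slot-bound).
# Each ConvNeXt block is dw_conv7 -> layer_norm -> pw_expand -> GELU ->
# pw_project -> residual (with a 1x1 shortcut projection when the block's
# input and output widths differ, as decoded plans generally force).

N_CLASSES <- 4L
ENC_BLOCKS <- c(1L, 2L, 2L, 6L, 2L)  # ConvNeXt blocks per encoder stage
STEM_STRIDE <- 4L                    # patchify stem
DOWN_FACTOR <- 64L                   # stride-4 stem + 4 stride-2 stages

#' Build the reference architecture from a channel plan
#'
#' Produces the deterministic layer table of the segmentation network whose
#' 43 tunable convolution layers are bound, in order, to the rows of
#' `plan`. The baseline plan reproduces the published UConvNeXt channel
#' column slot-for-slot.
#'
#' @param plan A [channel_plan()] with 43 rows; the `optimized` column
#'   supplies the slot widths.
#' @param input_size Spatial input size `c(H, W)` recorded on the spec
#'   (both divisible by 16); default `c(512, 512)`.
#' @return Object of class `"architecture_spec"`: list with `layers` (data
#'   frame: `kind`, `in_ch`, `out_ch`, `kernel`, `stride`, `padding`,
#'   `slot`, `res_div`, `block`, `skip`), `plan`, `n_classes`,
#'   `input_size`, `down_factor`.
#' @export
reference_spec <- function(plan, input_size = c(512, 512)) {
  stopifnot(inherits(plan, "channel_plan"))
  if (nrow(plan) != 43)
    stop("the reference topology requires a 43-entry channel plan")
  ch <- plan$optimized
  rows <- list()
  blk_id <- 0L
  add <- function(kind, in_ch, out_ch, kernel = 1L, stride = 1L,
                  padding = 0L, slot = NA_integer_, res_div = 1L,
                  block = NA_integer_, skip = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, in_ch = in_ch, out_ch = out_ch, kernel = kernel,
      stride = stride, padding = padding, slot = slot, res_div = res_div,
      block = block, skip = skip, stringsAsFactors = FALSE)
  }
  add_block <- function(c_in, slot_expand, slot_project, res_div) {
    blk_id <<- blk_id + 1L
    e <- ch[slot_expand]; p <- ch[slot_project]
    add("dw_conv7", c_in, c_in, 7L, 1L, 3L, res_div = res_div,
        block = blk_id)
    add("layer_norm", c_in, c_in, res_div = res_div, block = blk_id)
    add("pw_expand", c_in, e, slot = slot_expand, res_div = res_div,
        block = blk_id)
    add("pw_project", e, p, slot = slot_project, res_div = res_div,
        block = blk_id)
    if (c_in != p)
      add("shortcut_proj", c_in, p, res_div = res_div, block = blk_id)
    p
  }

  # ---- encoder ----
  slot <- 1L
  add("stem_conv7", 3L, ch[1], 7L, STEM_STRIDE, 3L, slot = 1L,
      res_div = STEM_STRIDE)
  cur <- ch[1]; slot <- 2L
  div <- STEM_STRIDE
  skip_ch <- integer(4)
  for (stage in seq_along(ENC_BLOCKS)) {
    if (stage > 1) {  # stride-2 downsample conv between stages
      add("downsample", cur, ch[slot], 2L, 2L, 0L, slot = slot,
          res_div = div * 2L)
      cur <- ch[slot]; slot <- slot + 1L; div <- div * 2L
    }
    for (b in seq_len(ENC_BLOCKS[stage])) {
      cur <- add_block(cur, slot, slot + 1L, div)
      slot <- slot + 2L
    }
    if (stage < 5) skip_ch[stage] <- cur
  }

  # ---- decoder ----
  for (level in 1:4) {
    sk <- 5L - level  # concat with encoder stage 4,3,2,1
    add("upsample_bilinear", cur, cur, res_div = div)
    div <- div / 2L
    add("concat_skip", cur, cur + skip_ch[sk], res_div = div,
        skip = paste0("s", sk))
    add("pw_reduce", cur + skip_ch[sk], ch[slot], slot = slot,
        res_div = div)
    cur <- ch[slot]; slot <- slot + 1L
    cur <- add_block(cur, slot, slot + 1L, div)
    slot <- slot + 2L
  }
  add("head_conv", cur, N_CLASSES, res_div = div)
  add("upsample_bilinear", N_CLASSES, N_CLASSES, res_div = div)
  add("upsample_bilinear", N_CLASSES, N_CLASSES, res_div = div / 2L)

  layers <- do.call(rbind, rows)
  slotted <- layers[!is.na(layers$slot), ]
  slotted <- slotted[order(slotted$slot), ]
  stopifnot(nrow(slotted) == 43,
            identical(as.integer(slotted$out_ch), plan$optimized))
  if (any(input_size %% DOWN_FACTOR != 0))
    stop("input size must be divisible by ", DOWN_FACTOR)
  structure(list(layers = layers, plan = plan, n_classes = N_CLASSES,
                 input_size = as.integer(input_size),
                 down_factor = DOWN_FACTOR),
            class = "architecture_spec")
}

conv_kinds <- c("stem_conv7", "downsample", "pw_expand", "pw_project",
                "pw_reduce", "shortcut_proj", "head_conv")

#' Count trainable parameters of an architecture
#'
#' Convolutions contribute `K^2 * Cin * Cout + Cout` (weights plus bias),
#' depthwise convolutions `K^2 * C + C`, layer normalization `2C` (affine
#' scale and shift); bilinear upsampling and concatenation are
#' parameter-free.
#'
#' @param spec An [reference_spec()] result.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  l <- spec$layers
  p <- numeric(nrow(l))
  cv <- l$kind %in% conv_kinds
  p[cv] <- l$kernel[cv]^2 * l$in_ch[cv] * l$out_ch[cv] + l$out_ch[cv]
  dw <- l$kind == "dw_conv7"
  p[dw] <- l$kernel[dw]^2 * l$out_ch[dw] + l$out_ch[dw]
  ln <- l$kind == "layer_norm"
  p[ln] <- 2 * l$out_ch[ln]
  sum(p)
}

#' Count forward-pass FLOPs of an architecture
#'
#' Counts multiply-accumulates of the convolutions as 2 FLOPs each:
#' `2 * K^2 * Cin * Cout * Hout * Wout` per convolution and
#' `2 * K^2 * C * Hout * Wout` per depthwise convolution, at the given
#' input resolution. Normalization, activation, upsampling and
#' concatenation are not counted (convention documented so model
#' comparisons are read as orderings).
#'
#' @param spec An [reference_spec()] result.
#' @param input_hw Spatial size `c(H, W)`, divisible by the total
#'   downsampling factor; defaults to the spec's `input_size`.
#' @return FLOPs (numeric scalar).
#' @export
count_flops <- function(spec, input_hw = spec$input_size) {
  if (any(input_hw %% spec$down_factor != 0))
    stop("input size must be divisible by ", spec$down_factor)
  l <- spec$layers
  hw <- (input_hw[1] / l$res_div) * (input_hw[2] / l$res_div)
  f <- numeric(nrow(l))
  cv <- l$kind %in% conv_kinds
  f[cv] <- 2 * l$kernel[cv]^2 * l$in_ch[cv] * l$out_ch[cv] * hw[cv]
  dw <- l$kind == "dw_conv7"
  f[dw] <- 2 * l$kernel[dw]^2 * l$out_ch[dw] * hw[dw]
  sum(f)
}

#' Describe an architecture as a layer table with per-layer costs
#'
#' @param spec An [reference_spec()] result.
#' @param input_hw Spatial size for the FLOP column.
#' @return Data frame: the layer table plus `params` and `flops` columns.
#' @export
describe_spec <- function(spec, input_hw = spec$input_size) {
  l <- spec$layers
  per <- lapply(seq_len(nrow(l)), function(i) {
    sub <- spec
    sub$layers <- l[i, , drop = FALSE]
    c(params = count_parameters(sub), flops = count_flops(sub, input_hw))
  })
  cbind(l, do.call(rbind, per))
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf(
    "architecture_spec: %d layers, %d tunable slots, %.2fM params, %.2fG FLOPs @ %dx%d\n",
    nrow(x$layers), sum(!is.na(x$layers$slot)),
    count_parameters(x) / 1e6, count_flops(x) / 1e9,
    x$input_size[1], x$input_size[2]))
  invisible(x)
}
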