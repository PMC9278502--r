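#' Render the static canvas
#'
#' Fills the canvas with the theme background color and pastes each
#' thumbnail at its layout position, in render order (later thumbnails draw
#' on top of earlier ones). Thumbnail pixels are composited unmodified; the
#' theme determines the background fill only.
#'
#' @param layout a [layout_result()].
#' @param thumbnails named list of `thumbnail` objects keyed by image id
#'   (every id in the layout must be present).
#' @param theme `"black"`, `"gray"` or `"dark_blue"`.
#' @param path optional output PNG path.
#' @return the canvas as a `height x width x 3` integer array in
#'   \[0, 255\], invisibly when `path` is given.
#' @export
render_static_canvas <- function(layout, thumbnails,
                                 theme = c("black", "gray", "dark_blue"),
                                 path = NULL) {
  theme <- match.arg(theme)
  stopifnot(inherits(layout, "layout_result"))
  ids <- layout$positions$image_id
  missing_ids <- setdiff(ids, names(thumbnails))
  if (length(missing_ids))
    stop(sprintf("no thumbnail for: %s", paste(missing_ids, collapse = ", ")),
         call. = FALSE)
  w <- as.integer(round(layout$canvas_dims[1]))
  h <- as.integer(round(layout$canvas_dims[2]))
  bg <- as.integer(round(hex_to_rgb(theme_color(theme))))
  canvas <- array(0L, c(h, w, 3L))
  for (p in 1:3) canvas[, , p] <- bg[p]
  pos <- layout$positions
  for (id in layout$render_order) {
    th <- thumbnails[[id]]
    i <- match(id, pos$image_id)
    x0 <- as.integer(round(pos$x[i])); y0 <- as.integer(round(pos$y[i]))
    td <- dim(th$rgb_tile)
    if (x0 < 0 || y0 < 0 || x0 + td[2] > w || y0 + td[1] > h)
      stop(sprintf("tile '%s' exceeds the canvas bounds", id), call. = FALSE)
    canvas[y0 + seq_len(td[1]), x0 + seq_len(td[2]), ] <- th$rgb_tile
  }
  if (!is.null(path)) {
    png::writePNG(canvas / 255, path)
    return(invisible(canvas))
  }
  canvas
}

#' Stack montage of a single multiplexed image
#'
#' Renders every channel of one image as its own cleaned single-channel
#' thumbnail in the channel's display color, arranged in a grid with the
#' marker name printed beneath each tile — one tile per channel, in channel
#' order.
#'
#' @param image a [multiplex_image()].
#' @param params a [clean_params()].
#' @param palette optional named marker color map (default categorical
#'   cycle in channel order).
#' @param tile_edge maximum tile edge (px).
#' @param grid_cols tiles per row (default: near-square grid).
#' @param theme canvas theme.
#' @param path optional output PNG path.
#' @return an object of class `stack_montage`: list with `canvas`
#'   (h x w x 3 integer array), `tiles` (list of `thumbnail`, one per
#'   channel, `source_id` = marker name), `labels` (`marker_names`) and
#'   `grid` (`c(rows, cols)`).
#' @export
stack_montage <- function(image, params = clean_params(), palette = NULL,
                          tile_edge = 222, grid_cols = NULL,
                          theme = c("black", "gray", "dark_blue"),
                          path = NULL) {
  theme <- match.arg(theme)
  stopifnot(inherits(image, "multiplex_image"))
  markers <- image$marker_names
  n <- length(markers)
  pal <- stats::setNames(default_palette(n), markers)
  if (!is.null(palette)) {
    known <- intersect(names(palette), markers)
    pal[known] <- palette[known]
  }
  tiles <- vector("list", n)
  for (i in seq_len(n)) {
    comp <- composite_channels(image, markers[i], params = params,
                               palette = pal[markers[i]])
    th <- make_thumbnail(comp, max_edge = tile_edge)
    th$source_id <- markers[i]
    th$out_name <- paste0(image$image_id, "_", markers[i], ".png")
    tiles[[i]] <- th
  }
  if (is.null(grid_cols)) grid_cols <- ceiling(sqrt(n))
  grid_rows <- ceiling(n / grid_cols)
  td <- dim(tiles[[1]]$rgb_tile)[1:2]
  gap <- 10L; label_h <- 11L           # 7-px glyphs + padding
  cell_h <- td[1] + label_h + gap
  cell_w <- td[2] + gap
  w <- gap + grid_cols * cell_w
  h <- gap + grid_rows * cell_h
  bg <- as.integer(round(hex_to_rgb(theme_color(theme))))
  canvas <- array(0L, c(h, w, 3L))
  for (p in 1:3) canvas[, , p] <- bg[p]
  for (i in seq_len(n)) {
    rr <- (i - 1L) %/% grid_cols; cc <- (i - 1L) %% grid_cols
    y0 <- gap + rr * cell_h; x0 <- gap + cc * cell_w
    tdi <- dim(tiles[[i]]$rgb_tile)
    canvas[y0 + seq_len(tdi[1]), x0 + seq_len(tdi[2]), ] <- tiles[[i]]$rgb_tile
    lab <- render_label_bitmap(markers[i])
    lw <- min(ncol(lab), td[2])
    ly <- y0 + tdi[1] + 2L
    for (p in 1:3) {
      region <- canvas[ly + seq_len(7L), x0 + seq_len(lw), p]
      region[lab[, seq_len(lw), drop = FALSE] == 1L] <- 255L
      canvas[ly + seq_len(7L), x0 + seq_len(lw), p] <- region
    }
  }
  out <- structure(list(canvas = canvas, tiles = tiles, labels = markers,
                        grid = c(grid_rows, grid_cols)),
                   class = "stack_montage")
  if (!is.null(path)) png::writePNG(canvas / 255, path)
  out
}

#' @export
print.stack_montage <- function(x, ...) {
  cat(sprintf("<stack_montage> %d tile(s) in a %d x %d grid\n",
              length(x$tiles), x$grid[1], x$grid[2]))
  invisible(x)
}

#' Build the interactive live-canvas scatterplot
#'
#' Writes a self-contained HTML document: one scatterplot view per metadata
#' category (selectable), every image a dot colored by the category's value
#' (the metadata's own color map when provided, else the default palette),
#' uncolored when no metadata exists. Hovering a point shows its full
#' record — image name, thumbnail name, coordinates and all metadata — and
#' the toolbar offers pan (drag), wheel zoom, box zoom (shift-drag), save
#' to PNG and reset.
#'
#' @param coords tibble with `image_id`, `x`, `y` covering every image.
#' @param metadata optional `cohort_metadata`.
#' @param path output HTML path.
#' @param category initial category to display (default: first available).
#' @param title document title.
#' @return `path`, invisibly; the assembled records are attached as
#'   attribute `records`.
#' @export
build_live_scatter <- function(coords, metadata = NULL, path,
                               category = NULL, title = "Live canvas") {
  stopifnot(all(c("image_id", "x", "y") %in% names(coords)))
  if (is.null(metadata)) metadata <- read_metadata_dir(NULL)
  cats <- metadata_categories(metadata)
  if (!is.null(category) && !category %in% cats) {
    warning(sprintf("metadata category '%s' absent; rendering uncolored",
                    category), call. = FALSE)
    category <- NULL
  }
  if (is.null(category) && length(cats)) category <- cats[1]
  records <- lapply(seq_len(nrow(coords)), function(i) {
    id <- coords$image_id[i]
    ann <- dplyr::filter(metadata$annotations, .data$image_id == !!id)
    meta <- stats::setNames(as.list(ann$value), ann$category)
    list(id = id, thumb = paste0(id, ".png"),
         x = coords$x[i], y = coords$y[i], meta = meta)
  })
  colormaps <- lapply(cats, function(cat)
    as.list(annotation_colors(metadata, cat, coords$image_id)))
  names(colormaps) <- cats
  payload <- jsonlite::toJSON(
    list(points = records, categories = as.list(cats),
         colors = colormaps,
         initial = if (is.null(category)) "" else category),
    auto_unbox = TRUE, null = "null", digits = NA)
  html <- sub("__TITLE__", title, live_canvas_template(), fixed = TRUE)
  html <- sub("__DATA__", payload, html, fixed = TRUE)
  writeLines(html, path)
  invisible(structure(path, records = records))
}

live_canvas_template <- function() {
'<!DOCTYPE html>
<html><head><meta charset="utf-8"><title>__TITLE__</title>
<style>
body { font-family: sans-serif; background: #181818; color: #ddd; margin: 12px; }
#toolbar { margin-bottom: 8px; }
button, select { background:#333; color:#ddd; border:1px solid #555; padding:3px 8px; }
#plot { background: #101010; border: 1px solid #444; }
#tooltip { position: absolute; display: none; background: #222; color: #eee;
  border: 1px solid #666; padding: 6px 8px; font-size: 12px; pointer-events: none;
  white-space: pre; z-index: 10; }
.pt { stroke: #888; stroke-width: 0.5; }
#legend span { margin-right: 12px; }
</style></head>
<body>
<h3>__TITLE__</h3>
<div id="toolbar">
  category: <select id="cat"></select>
  <button id="reset">reset</button>
  <button id="save">save png</button>
  <span style="font-size:12px">drag = pan, wheel = zoom, shift-drag = box zoom, hover = metadata</span>
</div>
<svg id="plot" width="820" height="620" viewBox="0 0 820 620"></svg>
<div id="legend"></div>
<div id="tooltip"></div>
<script>
var DATA = __DATA__;
var svg = document.getElementById("plot");
var W = 820, H = 620, M = 40;
var view = {x: 0, y: 0, w: W, h: H};
var xs = DATA.points.map(function(p){return p.x;});
var ys = DATA.points.map(function(p){return p.y;});
function rng(a){var lo=Math.min.apply(null,a),hi=Math.max.apply(null,a);
  if(lo===hi){lo-=1;hi+=1;} return [lo,hi];}
var xr = rng(xs), yr = rng(ys);
function sx(v){return M + (v - xr[0]) / (xr[1]-xr[0]) * (W - 2*M);}
function sy(v){return H - M - (v - yr[0]) / (yr[1]-yr[0]) * (H - 2*M);}
function colorOf(p, cat){
  if(!cat || !DATA.colors[cat]) return "#cccccc";
  var c = DATA.colors[cat][p.id];
  return c ? c : "#cccccc";
}
var cat = DATA.initial;
var sel = document.getElementById("cat");
var opts = [""].concat(DATA.categories);
opts.forEach(function(c){var o=document.createElement("option");
  o.value=c;o.textContent=c===""?"(none)":c;sel.appendChild(o);});
sel.value = cat;
sel.addEventListener("change", function(){cat = sel.value; draw();});
var tooltip = document.getElementById("tooltip");
function draw(){
  while(svg.firstChild) svg.removeChild(svg.firstChild);
  DATA.points.forEach(function(p){
    var c = document.createElementNS("http://www.w3.org/2000/svg","circle");
    c.setAttribute("cx", sx(p.x)); c.setAttribute("cy", sy(p.y));
    c.setAttribute("r", 5); c.setAttribute("class","pt");
    c.setAttribute("fill", colorOf(p, cat));
    c.addEventListener("mousemove", function(ev){
      var lines = ["image: " + p.id, "thumbnail: " + p.thumb,
                   "x: " + p.x, "y: " + p.y];
      for(var k in p.meta) lines.push(k + ": " + p.meta[k]);
      tooltip.textContent = lines.join("\\n");
      tooltip.style.left = (ev.pageX + 12) + "px";
      tooltip.style.top = (ev.pageY + 12) + "px";
      tooltip.style.display = "block";
    });
    c.addEventListener("mouseleave", function(){tooltip.style.display="none";});
    svg.appendChild(c);
  });
  var lg = document.getElementById("legend"); lg.innerHTML = "";
  if(cat && DATA.colors[cat]){
    var seen = {};
    DATA.points.forEach(function(p){
      var v = p.meta[cat]; if(v===undefined||seen[v])return; seen[v]=1;
      var s = document.createElement("span");
      s.innerHTML = "<svg width=12 height=12><circle cx=6 cy=6 r=5 fill=\'"+
        colorOf(p,cat)+"\'/></svg> " + v;
      lg.appendChild(s);
    });
  }
  setView();
}
function setView(){
  svg.setAttribute("viewBox", view.x+" "+view.y+" "+view.w+" "+view.h);
}
svg.addEventListener("wheel", function(ev){
  ev.preventDefault();
  var f = ev.deltaY < 0 ? 0.85 : 1/0.85;
  var r = svg.getBoundingClientRect();
  var mx = view.x + (ev.clientX - r.left)/r.width * view.w;
  var my = view.y + (ev.clientY - r.top)/r.height * view.h;
  view.x = mx - (mx - view.x)*f; view.y = my - (my - view.y)*f;
  view.w *= f; view.h *= f; setView();
});
var drag = null, box = null;
svg.addEventListener("mousedown", function(ev){
  if(ev.shiftKey){ box = {x0: ev.clientX, y0: ev.clientY}; }
  else drag = {x: ev.clientX, y: ev.clientY};
});
window.addEventListener("mousemove", function(ev){
  if(drag){
    var r = svg.getBoundingClientRect();
    view.x -= (ev.clientX - drag.x)/r.width * view.w;
    view.y -= (ev.clientY - drag.y)/r.height * view.h;
    drag = {x: ev.clientX, y: ev.clientY}; setView();
  }
});
window.addEventListener("mouseup", function(ev){
  if(box){
    var r = svg.getBoundingClientRect();
    var x1 = view.x + (Math.min(box.x0, ev.clientX)-r.left)/r.width*view.w;
    var x2 = view.x + (Math.max(box.x0, ev.clientX)-r.left)/r.width*view.w;
    var y1 = view.y + (Math.min(box.y0, ev.clientY)-r.top)/r.height*view.h;
    var y2 = view.y + (Math.max(box.y0, ev.clientY)-r.top)/r.height*view.h;
    if(x2-x1 > 5 && y2-y1 > 5){ view = {x:x1, y:y1, w:x2-x1, h:y2-y1}; setView(); }
    box = null;
  }
  drag = null;
});
document.getElementById("reset").addEventListener("click", function(){
  view = {x:0, y:0, w:W, h:H}; setView();
});
document.getElementById("save").addEventListener("click", function(){
  var xml = new XMLSerializer().serializeToString(svg);
  var img = new Image();
  img.onload = function(){
    var cv = document.createElement("canvas"); cv.width = W; cv.height = H;
    var ctx = cv.getContext("2d");
    ctx.fillStyle = "#101010"; ctx.fillRect(0,0,W,H);
    ctx.drawImage(img, 0, 0);
    var a = document.createElement("a");
    a.download = "live_canvas.png"; a.href = cv.toDataURL("image/png");
    a.click();
  };
  img.src = "data:image/svg+xml;base64," +
    btoa(unescape(encodeURIComponent(xml)));
});
draw();
</script>
</body></html>'
}
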