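# File formats

Column-by-column schemas for every file the package reads or writes.

## Calibration pairs (CSV, input to `calibrate` / `read_calibration_pairs()`)

| column | type | units | meaning |
|---|---|---|---|
| dx_um, dy_um, dz_um | numeric | µm | manipulator displacement of one calibration move |
| du_px, dv_px | numeric | px | annotated tip displacement in the image (u right, v down, 0-based, sub-pixel allowed) |

## Transform (JSON, output of `calibrate` / `write_transform()`)

`{"matrix": [6 floats, row-major 2x3, px/µm], "theta_rad": float,
"scale_px_per_um": float, "residual_rms_px": float}`

## Annotated path (CSV, input to `plan` / `read_annotated_path()`)

| column | type | units |
|---|---|---|
| u_px, v_px | numeric | px |

The interior side (`left`/`right` of the travel direction) comes from the
`--interior-side` flag or config, not the CSV.

## Trajectory plan (JSON, output of `plan` / `write_plan()`)

`{"params": {...}, "sites": [{site, arclength_um, axial_depth_um,
surface_x/y/z, approach_x/y/z, inject_x/y/z}], "commands": [{t_s, site,
kind: "pressure"|"approach"|"inject"|"dwell"|"retract", x_um, y_um, z_um,
state}]}` — `state` is the pressure in mbar for `pressure` commands and the
hold time in seconds for `dwell` commands, null otherwise.

## Session log (CSV, output of `simulate` / `write_session_log()`)

| column | type | units | meaning |
|---|---|---|---|
| site | integer | | site index in path order |
| t_s | numeric | s | attempt timestamp (injection command time) |
| pressure_mbar | numeric | mbar | constant line pressure |
| axial_depth_um | numeric | µm | axial penetration at this site |
| success | logical | | Bernoulli outcome |
| cell_id | character | | targeted cell, when a populated tissue is attached |

Summary JSON: `{n_attempts, n_success, success_pct, duration_min,
attempts_per_min, successes_per_min}`.

## Cell table (CSV, input to `analyze --cells` / `read_cell_table()`)

| column | type | meaning |
|---|---|---|
| id | character | unique cell id |
| x_um, y_um, z_um | numeric | nucleus position, stage µm |
| distance_um | numeric | nucleus distance from the ventricular surface (0 µm) |
| zone | character | VZ / SVZ / CP (anything else treated as unknown) |
| sox2, tbr2, tuj1, reelin, satb2, rfp, edu | character | pos / neg / unknown |
| dye_permeable | logical/0-1 | carries the junction-permeable dye (e.g. free Alexa-488) |
| dye_impermeable | logical/0-1 | carries the junction-impermeable dextran dye (injected cell) |
| dye_ly | logical/0-1 | Lucifer Yellow (neuron morphology tracer) |
| apical_contact | logical | has an apical process |
| pyknotic | logical | condensed (dying) nucleus |

Only the columns present are used; each analysis states its requirements.

## Attempt-log fixtures (CSV, from `genfix` / `make_benchmark_fixtures()`)

Same schema as the session log minus `cell_id` (column `depth_um` instead of
`axial_depth_um`); `site`, `t_s`, `pressure_mbar`, `depth_um`, `success`.

## Group comparison (CSV, input to `stats compare`)

| column | type | meaning |
|---|---|---|
| group | character | exactly two levels; the first plays the role of x |
| value | numeric | response |

Output JSON: `{n1, n2, U, p, method, alternative, group1, group2}`.

## Simulation config (JSON, input to `simulate`)

`{"seed": int, "path": {"u_px": [...], "v_px": [...], "interior_side":
"left"|"right"}, "transform": {"theta_rad": float, "scale_px_per_um":
float}, "params": {spacing_um, depth_um, pullout_um, pressure_mbar,
approach_angle_deg, speed_um_s, dwell_s}, "model": "depth"|"pressure"| or
an inline table [{pressure_mbar, depth_um, p}], "output_dir": "dir"}`

All fields have defaults except `seed` (defaults to 1 with a logged note).

## Frames

Single-channel 8-bit PNG (`write_frame()`), with a `.json` sidecar holding
the ground-truth tip pixel, in-FOV flag and projected surface polyline.

## Manifests

Every CLI run writes `<out>.manifest.json` (or `manifest.json` in the
output directory): `{subcommand, options, seed, config_hash}` — sufficient
to replay the run byte-identically.
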