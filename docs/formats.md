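# File formats

All formats are versioned with `"format_version": 1`. Unknown keys are
preserved by the readers and written back on save.

## Recipe (`recipe.json`)

A JSON dictionary of compartments, each with a list of ingredient
definitions (the CellPACK-heritage layout: a recipe is a dictionary
describing the proteins and their properties):

```json
{
  "format_version": 1,
  "name": "demo",
  "compartments": [
    {
      "name": "cytoplasm",
      "ingredients": [
        {
          "name": "blobulin",
          "kind": "soluble",                  // soluble | membrane_bound | fiber
          "sprite": "sprites/blobulin.png",   // RGBA PNG, path relative to the recipe
          "nm_per_pixel": 0.25,
          "color": "#F2A633",
          "binding": {                        // membrane_bound only
            "thickness": 4.0,                 // nm
            "surface_offset": 0.0,            // nm, protein center above membrane center
            "padding": 0.5,                   // nm
            "rotation": 0.0                   // rad
          },
          "fiber": {                          // fiber only
            "spacing": 10.0,                  // nm between subunit centers
            "subunit_rotation": 0.0,          // rad twist per subunit
            "n_springs": 10,                  // persistence springs (DNA 10, RNA 0, membrane 3)
            "angle_limit": null
          }
        }
      ]
    }
  ]
}
```

Legacy key spellings (`file`/`png`/`image` for `sprite`, `type` for `kind`,
`nmPerPixel` for `nm_per_pixel`) are accepted with a message.

## Scene (`scene.txt`)

Line-oriented JSON: one record per line, canonical order (header,
instances by id, chains, hinges, springs, pins, pin-tos, rails, groups,
locks, measurements, fills, backgrounds). Positions are nm with 3 decimals.
Loading restores exact poses (no settling); lock-region hulls are not stored
but recomputed deterministically from the member positions.

```text
{"type":"header","format_version":1,"canvas":[200,200],"background":[0.12,0.12,0.16],"seed":1}
{"type":"instance","id":1,"ingredient":"bilayer","color":"#8CCC80","position":[150,100],"angle":1.571,"layer":1}
{"type":"chain","id":1,"chain_type":"membrane","ingredient":"bilayer","spacing":10,"closed":true,"bodies":[1,2,3]}
{"type":"hinge","a":1,"b":2,"pa":[5,0],"pb":[-5,0],"chain":1}
{"type":"spring","a":1,"b":3,"rest":20,"stiffness":0.5,"chain":1}
{"type":"pin","id":7}
{"type":"pinto","a":8,"pa":[0,0],"b":9,"pb":[1,0],"dist":12.5}
{"type":"rail","body":10,"chain":1,"offset":0,"rotation":0}
{"type":"group","id":1,"members":[8,9],"ingredient":["blobulin","blobulin"],"layer":[0,0],"offsets":[[-5,0],[5,0]],"angles":[0,0]}
{"type":"lock","id":1,"members":[11,12],"bandwidth":8}
{"type":"measurement","a":8,"b":11}
{"type":"fill","chain":1,"name":"vesicle-1","color":"#8CCC80"}
{"type":"background","file":"tomo.png","nm_per_pixel":0.36,"opacity":0.5,"rotation":0,"z":0}
```

## Bundle (`.zip`)

A zip archive containing `scene.txt`, `recipe.json`, and every sprite PNG
under `sprites/`. Bundles are hermetic: they load in an empty directory.

## Session script

```json
{
  "seed": 1,
  "commands": [
    {"cmd": "new-scene", "width": 200, "height": 200},
    {"cmd": "fixture-recipe"},
    {"cmd": "paint", "ingredient": "blobulin", "position": [100, 100], "layer": 0},
    {"cmd": "draw-membrane", "ingredient": "bilayer", "points": [[50,50],[150,50],[150,150]]},
    {"cmd": "measure", "a": 1, "b": 2},
    {"cmd": "render", "file": "out.png", "pixels_per_nm": 0.5}
  ]
}
```

Verbs: `new-scene`, `ingredient`, `fixture-recipe`, `paint`, `draw-fiber`,
`draw-membrane`, `attach`, `pin`, `unpin`, `pin-to`, `group`, `stamp`,
`lock`, `unlock`, `nudge`, `erase`, `measure`, `diffuse`, `settle`,
`background`, `save`, `bundle`, `render`. The whole script is validated
before execution; the JSON-lines report (`report.jsonl`) carries one record
per command plus the live copy numbers and measurements after each one.

## Structures

PDB (fixed-column `ATOM`/`HETATM`, first model, optional `REMARK 350 BIOMT`
assembly expansion) and mmCIF (`_atom_site` loop, first model, asymmetric
unit). Elements map to standard van der Waals radii; CA-only traces get a
3 A per-residue pseudo-atom radius.
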