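{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "material-record.schema.json",
  "title": "Nanomaterial characterization record",
  "description": "One material's inputs to the tiered grouping framework. Units are fixed by the schema: mg/L (solubility, dissolution), nm (primary particle size, agglomerate diameter), um (fiber length/diameter), percent (mass fractions, biodistribution), ug/cm2 (epithelial LOEC), mm2/mL (macrophage LOEC), mg/m3 (STIS NOAEC), days (t50), mV (zeta potential), m2/g (surface area). Absent optional values mean 'not measured', never 0.",
  "type": "object",
  "required": ["material_id"],
  "additionalProperties": false,
  "properties": {
    "material_id": {"type": "string", "minLength": 1},
    "name": {"type": "string"},
    "notes": {"type": "string"},
    "intrinsic": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "water_solubility": {"type": "number", "minimum": 0},
        "primary_particle_size": {"type": "number", "minimum": 0},
        "aspect_ratio": {"type": "number", "minimum": 1},
        "length_um": {"type": "number", "minimum": 0},
        "diameter_um": {"type": "number", "minimum": 0},
        "shape_class": {"enum": ["globular", "platelet", "fiber_like", "other"]},
        "surface_area": {"type": "number", "minimum": 0},
        "surface_chemistry": {"type": "string"},
        "composition": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["name", "mass_fraction"],
            "additionalProperties": false,
            "properties": {
              "name": {"type": "string"},
              "mass_fraction": {"type": "number", "minimum": 0, "maximum": 100},
              "ghs_systemic": {"type": "boolean"}
            }
          }
        }
      }
    },
    "system": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "dissolution_biological": {"type": "number", "minimum": 0},
        "dissolution_medium": {"type": "string"},
        "surface_reactivity_relative": {"type": "number", "minimum": 0},
        "surface_reactivity_fras": {"type": "number", "minimum": 0},
        "aan": {"type": "number", "minimum": 1},
        "agglomerate_diameter": {"type": "number", "minimum": 0},
        "zeta_potential": {"type": "number"},
        "hydrophobicity_class": {"type": "string"}
      }
    },
    "invitro": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "epithelial_loec": {"type": "number", "exclusiveMinimum": 0},
        "epithelial_no_effect_up_to": {"type": "number", "exclusiveMinimum": 0},
        "macrophage_params": {
          "type": "object",
          "additionalProperties": false,
          "propertyNames": {"enum": ["ldh", "glucuronidase", "tnf_alpha", "ros"]},
          "patternProperties": {
            "": {
              "type": "object",
              "additionalProperties": false,
              "properties": {
                "loec_surface_area": {"type": "number", "minimum": 0},
                "no_effect": {"type": "boolean"}
              }
            }
          }
        }
      }
    },
    "invivo": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "stis_noaec": {"type": "number", "exclusiveMinimum": 0},
        "noaec_censoring": {"enum": ["exact", "at_least"]},
        "effects_regression_or_progression": {
          "enum": ["regression", "progression", "none", "unknown"]
        },
        "t50_days": {"type": "number", "exclusiveMinimum": 0},
        "biodistribution": {
          "type": "object",
          "additionalProperties": false,
          "properties": {
            "fraction_primary_organ": {"type": "number", "minimum": 0, "maximum": 100},
            "fraction_mps": {"type": "number", "minimum": 0, "maximum": 100},
            "fraction_beyond_mps": {"type": "number", "minimum": 0, "maximum": 100}
          }
        }
      }
    },
    "qualifiers": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "release_possible": {"enum": ["yes", "no", "unknown"]},
        "exposure_routes": {
          "type": "array",
          "items": {"enum": ["inhalation", "oral", "dermal", "ocular"]}
        },
        "use_stage_notes": {"type": "string"},
        "dustiness_class": {"type": "string"}
      }
    }
  }
}
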