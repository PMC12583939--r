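{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/fhir/soa/soa-graph-schema.json",
  "title": "Native SoA graph document",
  "type": "object",
  "required": ["graphID", "title", "nodes", "edges"],
  "properties": {
    "graphID": { "type": "string" },
    "title": { "type": "string" },
    "nodes": { "type": "array", "items": { "$ref": "#/definitions/node" } },
    "edges": { "type": "array", "items": { "$ref": "#/definitions/edge" } },
    "activitySubgraphs": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["nodes", "edges"],
        "properties": {
          "nodes": { "type": "array", "items": { "$ref": "#/definitions/node" } },
          "edges": { "type": "array", "items": { "$ref": "#/definitions/edge" } }
        }
      }
    },
    "metadata": { "type": "object" }
  },
  "definitions": {
    "window": {
      "type": "object",
      "required": ["earlier", "later"],
      "properties": {
        "earlier": { "type": "integer", "minimum": 0 },
        "later": { "type": "integer", "minimum": 0 }
      }
    },
    "node": {
      "type": "object",
      "required": ["id", "alias", "type", "name", "referenceTimepoint", "role"],
      "properties": {
        "id": { "type": "string" },
        "alias": { "type": "string" },
        "type": { "enum": ["interaction", "activity"] },
        "subtype": { "type": "string" },
        "name": { "type": "string" },
        "description": { "type": "string" },
        "plannedTiming": { "type": "integer" },
        "referenceTimepoint": { "type": "boolean" },
        "plannedWindow": { "$ref": "#/definitions/window" },
        "plannedDuration": { "type": "number" },
        "role": {
          "enum": ["regular", "instantiation_start", "instantiation_finish",
                   "activity_start", "activity_finish",
                   "cycle_start", "cycle_finish", "unscheduled"]
        }
      }
    },
    "edge": {
      "type": "object",
      "required": ["id", "source", "target", "transitionDelay",
                   "transitionType", "primaryPath", "origin"],
      "properties": {
        "id": { "type": "string" },
        "source": { "type": "string" },
        "target": { "type": "string" },
        "transitionDelay": { "type": "integer" },
        "transitionWindow": { "$ref": "#/definitions/window" },
        "transitionType": {
          "enum": ["start_to_start", "start_to_finish",
                   "finish_to_start", "finish_to_finish"]
        },
        "transitionRule": {
          "type": "string",
          "description": "Conditional-scheduling rule text, media type text/x-soa-rule"
        },
        "primaryPath": { "type": "boolean" },
        "origin": { "enum": ["explicit", "implied"] }
      }
    }
  }
}
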