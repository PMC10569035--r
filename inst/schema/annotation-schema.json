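{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "tpcurate annotation document",
  "description": "PUG-View-style annotation dialect consumed by parse_annotation_json(). Offsets are 0-based, length-counted, in Unicode code points.",
  "type": "object",
  "required": ["Annotations"],
  "properties": {
    "Annotations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["SourceName", "SourceID", "CID", "Data"],
        "properties": {
          "SourceName": {"type": "string"},
          "SourceID": {"type": "string"},
          "Name": {"type": "string"},
          "CID": {"type": "integer", "minimum": 1},
          "Data": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["Value"],
              "properties": {
                "Value": {
                  "type": "object",
                  "required": ["StringWithMarkup"],
                  "properties": {
                    "StringWithMarkup": {
                      "type": "array",
                      "items": {
                        "type": "object",
                        "required": ["String"],
                        "properties": {
                          "String": {"type": "string", "minLength": 1},
                          "Markup": {
                            "type": "array",
                            "items": {
                              "type": "object",
                              "required": ["Start", "Length"],
                              "properties": {
                                "Start": {"type": "integer", "minimum": 0},
                                "Length": {"type": "integer", "minimum": 1},
                                "CID": {"type": "integer", "minimum": 1},
                                "Text": {"type": "string"}
                              }
                            }
                          }
                        }
                      }
                    }
                  }
                }
              }
            }
          }
        }
      }
    }
  }
}
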