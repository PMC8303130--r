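{
  "format_version": "1.0",
  "variables": [
    {
      "name": "Flood",
      "states": [
        "present",
        "absent"
      ]
    },
    {
      "name": "LOSI",
      "states": [
        "present",
        "absent"
      ]
    },
    {
      "name": "PPD",
      "states": [
        "present",
        "absent"
      ]
    },
    {
      "name": "Lsever",
      "states": [
        "present",
        "absent"
      ]
    },
    {
      "name": "Msever",
      "states": [
        "present",
        "absent"
      ]
    }
  ],
  "arcs": [
    {
      "parent": "Flood",
      "child": "LOSI"
    },
    {
      "parent": "LOSI",
      "child": "PPD"
    },
    {
      "parent": "PPD",
      "child": "Lsever"
    },
    {
      "parent": "PPD",
      "child": "Msever"
    }
  ],
  "cpts": [
    {
      "child": "Flood",
      "parents": [],
      "rows": {
        "1": [0.20100000000000001, 0.79899999999999993]
      }
    },
    {
      "child": "LOSI",
      "parents": [
        "Flood"
      ],
      "rows": {
        "present": [1, 0],
        "absent": [0.52440550688360454, 0.47559449311639546]
      }
    },
    {
      "child": "PPD",
      "parents": [
        "LOSI"
      ],
      "rows": {
        "present": [0.2296296296296296, 0.77037037037037037],
        "absent": [0.1148148148148148, 0.88518518518518519]
      }
    },
    {
      "child": "Lsever",
      "parents": [
        "PPD"
      ],
      "rows": {
        "present": [0.81450252951096125, 0.18549747048903875],
        "absent": [0.40725126475548062, 0.59274873524451932]
      }
    },
    {
      "child": "Msever",
      "parents": [
        "PPD"
      ],
      "rows": {
        "present": [0.35581787521079261, 0.64418212478920744],
        "absent": [0.17790893760539631, 0.82209106239460372]
      }
    }
  ]
}
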