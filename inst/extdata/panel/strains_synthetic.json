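{
  "BW25113": {
    "background": "K-12",
    "deletions": [],
    "additions": []
  },
  "R1": {
    "background": "R1",
    "deletions": [],
    "additions": []
  },
  "R2": {
    "background": "R2",
    "deletions": [],
    "additions": []
  },
  "R3": {
    "background": "R3",
    "deletions": [],
    "additions": []
  },
  "R4": {
    "background": "R4",
    "deletions": [],
    "additions": []
  },
  "ClearColi": {
    "background": "ClearColi",
    "deletions": [],
    "additions": []
  },
  "BW_dwaaL": {
    "background": "K-12",
    "deletions": [
      "waaL"
    ],
    "additions": []
  },
  "BW_dwaaU": {
    "background": "K-12",
    "deletions": [
      "waaU"
    ],
    "additions": []
  },
  "BW_dwaaR": {
    "background": "K-12",
    "deletions": [
      "waaR"
    ],
    "additions": []
  },
  "BW_dwaaO": {
    "background": "K-12",
    "deletions": [
      "waaO"
    ],
    "additions": []
  },
  "BW_dwaaB": {
    "background": "K-12",
    "deletions": [
      "waaB"
    ],
    "additions": []
  },
  "BW_dwaaG": {
    "background": "K-12",
    "deletions": [
      "waaG"
    ],
    "additions": []
  },
  "BW_dwaaQ": {
    "background": "K-12",
    "deletions": [
      "waaQ"
    ],
    "additions": []
  },
  "BW_dwaaY": {
    "background": "K-12",
    "deletions": [
      "waaY"
    ],
    "additions": []
  },
  "BW_dwaaP": {
    "background": "K-12",
    "deletions": [
      "waaP"
    ],
    "additions": []
  },
  "BW_dwaaF": {
    "background": "K-12",
    "deletions": [
      "waaF"
    ],
    "additions": []
  },
  "BW_dwaaC": {
    "background": "K-12",
    "deletions": [
      "waaC"
    ],
    "additions": []
  },
  "BW_dwaaE": {
    "background": "K-12",
    "deletions": [
      "waaE"
    ],
    "additions": []
  },
  "BW_dgmhD": {
    "background": "K-12",
    "deletions": [
      "gmhD"
    ],
    "additions": []
  },
  "BW_pWaaK": {
    "background": "K-12",
    "deletions": [],
    "additions": [
      "R2:waaK"
    ]
  },
  "BW_pWaaID": {
    "background": "K-12",
    "deletions": [],
    "additions": [
      "R3:waaI",
      "R3:waaD"
    ]
  },
  "BW_pWaaX": {
    "background": "K-12",
    "deletions": [],
    "additions": [
      "R4:waaX"
    ]
  },
  "BW_dwaaR_pWaaT": {
    "background": "K-12",
    "deletions": [
      "waaR"
    ],
    "additions": [
      "R1:waaT"
    ]
  },
  "BW_dwaaR_pWaaTW": {
    "background": "K-12",
    "deletions": [
      "waaR"
    ],
    "additions": [
      "R1:waaT",
      "R1:waaW"
    ]
  },
  "BW_dwaaR_pWaaX": {
    "background": "K-12",
    "deletions": [
      "waaR"
    ],
    "additions": [
      "R4:waaX"
    ]
  }
}
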