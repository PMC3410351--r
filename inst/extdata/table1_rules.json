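{
  "name": "table1",
  "rules": [
    {
      "conditions": [
        {"feature": "nse_count", "kind": "interval", "low": 3, "high": 5, "average": 4.4}
      ],
      "predicted": "healthy"
    },
    {
      "conditions": [
        {"feature": "orientation_time_s", "kind": "interval", "low": 294.0, "high": 349.51, "average": 320.84},
        {"feature": "total_time_s", "kind": "interval", "low": 354.95, "high": 407.0, "average": 376.29}
      ],
      "predicted": "healthy"
    },
    {
      "conditions": [
        {"feature": "atc_count", "kind": "exact_count", "low": 3, "high": 3}
      ],
      "predicted": "healthy"
    },
    {
      "conditions": [
        {"feature": "licking_count", "kind": "interval", "low": 21, "high": 56, "average": 34.5},
        {"feature": "nse_count", "kind": "interval", "low": 6, "high": 17, "average": 4.4}
      ],
      "predicted": "healthy"
    },
    {
      "conditions": [
        {"feature": "nse_count", "kind": "interval", "low": 1, "high": 2, "average": 100.4}
      ],
      "predicted": "healthy"
    },
    {
      "conditions": [
        {"feature": "vibration_time_s", "kind": "interval", "low": 0, "high": 77.0, "average": 15.72},
        {"feature": "nse_count", "kind": "interval", "low": 35, "high": 51, "average": 43.43}
      ],
      "predicted": "healthy"
    },
    {
      "conditions": [
        {"feature": "total_time_s", "kind": "interval", "low": 516.58, "high": 519.91, "average": 517.94}
      ],
      "predicted": "healthy"
    }
  ]
}
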