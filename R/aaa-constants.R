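## Transport modes, in fixed order: M1 = walking, M2 = cycling,
## M3 = public_transport.
MODES <- c("walking", "cycling", "public_transport")

## Population column per mode in a communities table.
POP_COLS <- c(
  walking          = "pop_walking",
  cycling          = "pop_cycling",
  public_transport = "pop_transit"
)

## Accessibility column per mode (plus the integrated score) in result tables.
ACCESS_COLS <- c(
  walking          = "access_walking",
  cycling          = "access_cycling",
  public_transport = "access_transit",
  integrated       = "access_integrated"
)
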