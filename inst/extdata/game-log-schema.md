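# Game-log JSON Lines schema

One JSON object per line. Coordinates are 0-based `(row, col)`, row-major,
origin at the top-left of the grid; `null` positions mark players in the
time-out zone. Player ids are 1-based and match the roster order.

## Line 1 — header

```json
{"type": "config",
 "config": {"grid_size": 10, "n_players": 5, "n_turns": 100,
            "star_spawn_prob": 0.75, "star_expire_prob": 0.05,
            "timeout_turns": 3, "group_type": "groups",
            "behavior_mix": "mixed", "turn_order": [1,2,3,4,5],
            "seed": 42, "zap_ray": "through", "distance_divisor": 10,
            "n_stars_init": 1},
 "players": [{"player_id": 1, "role": "participant", "policy": "avoider",
              "team": "blue", "relation": "self"}, "..."]}
```

## Lines 2+ — turn records

One record per player action; players in time-out emit no record. All state
fields are the **pre-action** snapshot.

| field          | type              | meaning                                   |
|----------------|-------------------|-------------------------------------------|
| `type`         | `"turn"`          | record marker                             |
| `round`        | int               | 1-based round index                       |
| `actor`        | int               | acting player id                          |
| `action`       | `"move"`/`"zap"`  | action kind                               |
| `dir`          | `"up"/"down"/"left"/"right"` | action direction               |
| `zapped`       | int array         | ids hit by the ray (empty for moves)      |
| `star_collected` | bool            | move landed on a star                     |
| `pos`          | array of `[row, col]` or `null` | all players' positions      |
| `timeout`      | int array         | remaining time-out rounds per player      |
| `score`        | int array         | stars collected so far per player         |
| `stars`        | array of `[row, col]` | star cells on the board               |

Written by `write_game_log()`, read by `read_game_log()`; identical
`(config, policies, seed)` produce byte-identical files.
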