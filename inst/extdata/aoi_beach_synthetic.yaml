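picture_id: beach
screen:
  width_px: 1680.0
  height_px: 1050.0
regions:
- label: family_sandcastle
  role: active_agent
  vertices:
  - - 345.1
    - 227.1
  - - 217.4
    - 254.0
  - - 86.1
    - 242.6
  - - 120.8
    - 140.6
  - - 198.8
    - 55.3
  - - 291.8
    - 130.4
- label: woman_reading
  role: active_agent
  vertices:
  - - 765.1
    - 227.1
  - - 640.5
    - 287.5
  - - 506.1
    - 242.6
  - - 503.0
    - 126.1
  - - 618.8
    - 55.3
  - - 746.5
    - 111.5
- label: guitar
  role: static_object
  vertices:
  - - 1185.1
    - 227.1
  - - 1059.3
    - 274.3
  - - 926.1
    - 242.6
  - - 937.8
    - 131.8
  - - 1038.8
    - 55.3
  - - 1152.9
    - 118.9
- label: parasol
  role: static_object
  vertices:
  - - 1605.1
    - 227.1
  - - 1479.6
    - 277.9
  - - 1346.1
    - 242.6
  - - 1353.8
    - 130.2
  - - 1458.8
    - 55.3
  - - 1576.6
    - 116.9
- label: barking_dog
  role: active_agent
  vertices:
  - - 345.1
    - 577.1
  - - 217.7
    - 607.6
  - - 86.1
    - 592.6
  - - 116.7
    - 489.1
  - - 198.8
    - 405.3
  - - 295.5
    - 478.4
- label: couple_walking
  role: active_agent
  vertices:
  - - 765.1
    - 577.1
  - - 640.5
    - 637.5
  - - 506.1
    - 592.6
  - - 503.0
    - 476.1
  - - 618.8
    - 405.3
  - - 746.5
    - 461.5
- label: friends_volleyball
  role: active_agent
  vertices:
  - - 1185.1
    - 577.1
  - - 1056.8
    - 598.0
  - - 926.1
    - 592.6
  - - 967.6
    - 493.2
  - - 1038.8
    - 405.3
  - - 1125.6
    - 483.8
- label: sea
  role: static_object
  vertices:
  - - 1605.1
    - 577.1
  - - 1479.6
    - 627.9
  - - 1346.1
    - 592.6
  - - 1353.8
    - 480.2
  - - 1458.8
    - 405.3
  - - 1576.6
    - 466.9
- label: yacht
  role: static_object
  vertices:
  - - 345.1
    - 927.1
  - - 219.8
    - 979.1
  - - 86.1
    - 942.6
  - - 92.4
    - 829.7
  - - 198.8
    - 755.3
  - - 317.8
    - 816.2
- label: seagulls
  role: active_agent
  vertices:
  - - 765.1
    - 927.1
  - - 637.5
    - 955.2
  - - 506.1
    - 942.6
  - - 539.5
    - 840.1
  - - 618.8
    - 755.3
  - - 713.0
    - 829.7
- label: condominiums
  role: static_object
  vertices:
  - - 1185.1
    - 927.1
  - - 1057.6
    - 956.4
  - - 926.1
    - 942.6
  - - 958.1
    - 839.6
  - - 1038.8
    - 755.3
  - - 1134.3
    - 829.0
- label: mountain
  role: static_object
  vertices:
  - - 1605.1
    - 927.1
  - - 1476.9
    - 949.2
  - - 1346.1
    - 942.6
  - - 1386.2
    - 842.7
  - - 1458.8
    - 755.3
  - - 1546.8
    - 833.1
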