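picture_id: han_river
screen:
  width_px: 1680.0
  height_px: 1050.0
regions:
- label: family_lunch
  role: active_agent
  vertices:
  - - 345.1
    - 227.1
  - - 220.1
    - 282.7
  - - 86.1
    - 242.6
  - - 88.4
    - 128.1
  - - 198.8
    - 55.3
  - - 321.5
    - 114.2
- label: girl_lawn
  role: active_agent
  vertices:
  - - 765.1
    - 227.1
  - - 637.5
    - 255.2
  - - 506.1
    - 242.6
  - - 539.5
    - 140.1
  - - 618.8
    - 55.3
  - - 713.0
    - 129.7
- label: girl_music
  role: active_agent
  vertices:
  - - 1185.1
    - 227.1
  - - 1059.8
    - 279.1
  - - 926.1
    - 242.6
  - - 932.4
    - 129.7
  - - 1038.8
    - 55.3
  - - 1157.8
    - 116.2
- label: boy_kicking_ball
  role: active_agent
  vertices:
  - - 1605.1
    - 227.1
  - - 1480.0
    - 281.5
  - - 1346.1
    - 242.6
  - - 1349.7
    - 128.7
  - - 1458.8
    - 55.3
  - - 1580.3
    - 114.8
- label: boy_dog_ball
  role: active_agent
  vertices:
  - - 345.1
    - 577.1
  - - 219.6
    - 627.9
  - - 86.1
    - 592.6
  - - 93.8
    - 480.2
  - - 198.8
    - 405.3
  - - 316.6
    - 466.9
- label: friends_photo
  role: active_agent
  vertices:
  - - 765.1
    - 577.1
  - - 637.7
    - 607.6
  - - 506.1
    - 592.6
  - - 536.7
    - 489.1
  - - 618.8
    - 405.3
  - - 715.5
    - 478.4
- label: man_drinking
  role: active_agent
  vertices:
  - - 1185.1
    - 577.1
  - - 1058.9
    - 619.5
  - - 926.1
    - 592.6
  - - 943.2
    - 483.9
  - - 1038.8
    - 405.3
  - - 1147.9
    - 471.6
- label: man_running
  role: active_agent
  vertices:
  - - 1605.1
    - 577.1
  - - 1477.8
    - 608.8
  - - 1346.1
    - 592.6
  - - 1375.4
    - 488.6
  - - 1458.8
    - 405.3
  - - 1556.8
    - 477.7
- label: bikers
  role: active_agent
  vertices:
  - - 345.1
    - 927.1
  - - 217.5
    - 955.2
  - - 86.1
    - 942.6
  - - 119.5
    - 840.1
  - - 198.8
    - 755.3
  - - 293.0
    - 829.7
- label: yacht
  role: static_object
  vertices:
  - - 765.1
    - 927.1
  - - 639.8
    - 979.1
  - - 506.1
    - 942.6
  - - 512.4
    - 829.7
  - - 618.8
    - 755.3
  - - 737.8
    - 816.2
- label: buildings
  role: static_object
  vertices:
  - - 1185.1
    - 927.1
  - - 1060.3
    - 985.1
  - - 926.1
    - 942.6
  - - 925.7
    - 827.1
  - - 1038.8
    - 755.3
  - - 1164.0
    - 812.8
- label: tree
  role: static_object
  vertices:
  - - 1605.1
    - 927.1
  - - 1479.8
    - 979.1
  - - 1346.1
    - 942.6
  - - 1352.4
    - 829.7
  - - 1458.8
    - 755.3
  - - 1577.8
    - 816.2
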