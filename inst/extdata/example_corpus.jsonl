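{"tweet_id":"t00000001","user_id":"u000018","created_at":"2022-04-05T02:16:00Z","text":"w270 w098 w270 w362 w270 w473 w009 w118 w079 w069 w270 w279 w437 w402 w124 w473"}
{"tweet_id":"t00000002","user_id":"u000017","created_at":"2022-01-28T10:32:54Z","text":"@u7961 w043 w118 w375 w162 w375 w162 w375 w124 w043 w162 w043 w043 w162 w375 w375 w419 https://t.co/vjzwlxv61v"}
{"tweet_id":"t00000003","user_id":"u000016","created_at":"2020-03-14T00:05:04Z","text":"w270 w124 w256 w065 w135 w124 w246 w404 w043 w358 w436 w436 w079 w278 w121 w382"}
{"tweet_id":"t00000004","user_id":"u000008","created_at":"2022-04-15T07:52:24Z","text":"w118 w027 w027 w402 w118 w434 w118 w434 w252 w118 w473 w419 w257 w419 zinc w473"}
{"tweet_id":"t00000005","user_id":"u000004","created_at":"2022-03-24T21:10:08Z","text":"w279 w456 w375 w420 w375 w118 vitamin d superb w043 w473 w043 w402 w420 w419 w118 w118"}
{"tweet_id":"t00000006","user_id":"u000013","created_at":"2022-02-18T13:41:46Z","text":"w420 w334 w118 w118 w043 w420 w004 w004 w043 w118 w497 w198 w183 w452 w497 w260"}
{"tweet_id":"t00000007","user_id":"u000002","created_at":"2020-12-25T22:49:57Z","text":"w118 w043 w162 w279 w043 w043 w043 w043 w162 w240 w403 w118 w162 w188 w057 w043"}
{"tweet_id":"t00000008","user_id":"u000020","created_at":"2021-02-27T21:19:55Z","text":"w118 w260 w402 w402 w175 w118 w118 w452 w118 w473 w402 w420 w420 w473 w118 w118"}
{"tweet_id":"t00000009","user_id":"u000001","created_at":"2020-12-13T11:35:19Z","text":"w118 w358 w266 w118 w121 w359 w402 w473 w473 w414 w279 w118 w118 w324 w118 w118"}
{"tweet_id":"t00000010","user_id":"u000015","created_at":"2021-05-09T22:04:59Z","text":"w118 w473 w118 w118 w473 w118 w473 w118 w473 w118 w260 w118 w473 w118 w118 w118"}
{"tweet_id":"t00000011","user_id":"u000008","created_at":"2021-12-24T00:46:06Z","text":"@u7113 w358 w108 w124 w082 w266 w474 w394 w266 w488 w491 w135 w108 w079 w118 w295 w079"}
{"tweet_id":"t00000012","user_id":"u000007","created_at":"2021-07-18T02:58:23Z","text":"@u9579 w324 w324 w419 w079 w262 w419 w124 w124 w466 w079 w180 w324 w162 w358 w135 w324 https://t.co/ot05faedee"}
{"tweet_id":"t00000013","user_id":"u000001","created_at":"2020-06-21T00:01:20Z","text":"@u6225 w043 w043 w419 w162 w420 w279 w162 w162 w162 w375 w043 w240 w043 w004 w240 w118"}
{"tweet_id":"t00000014","user_id":"u000004","created_at":"2020-12-10T20:11:37Z","text":"w270 w118 w135 w257 zpack w270 w124 w183 w135 w121 w473 w098 w079 w079 w266 w118"}
{"tweet_id":"t00000015","user_id":"u000002","created_at":"2021-11-15T11:34:38Z","text":"@u9594 w043 w121 w266 w188 w118 w480 w162 w162 w118 w497 w043 w162 w473 w474 w403 w043"}
{"tweet_id":"t00000016","user_id":"u000019","created_at":"2021-09-01T03:06:40Z","text":"w270 w124 w473 w402 w402 w270 w118 w121 w135 w135 w118 w118 w043 w402 w139 w402"}
{"tweet_id":"t00000017","user_id":"u000017","created_at":"2021-05-29T14:00:01Z","text":"w279 w403 w043 w079 w247 w474 w079 w270 w270 w480 w043 w375 w135 w491 w004 w334"}
{"tweet_id":"t00000018","user_id":"u000014","created_at":"2021-11-30T01:25:57Z","text":"@u9894 w473 w240 w419 w186 w420 w027 w420 w118 w497 w162 w456 w419 w118 w419 w420 w419"}
{"tweet_id":"t00000019","user_id":"u000012","created_at":"2021-06-01T18:42:15Z","text":"w324 w373 w266 w358 w043 w324 w382 w375 w065 w121 w043 w121 w266 w118 w373 w334"}
{"tweet_id":"t00000020","user_id":"u000006","created_at":"2021-12-24T20:44:59Z","text":"w375 w375 w118 w118 w118 w162 w118 w118 w375 w118 w118 w118 w473 w089 w403 w402"}
{"tweet_id":"t00000021","user_id":"u000001","created_at":"2020-10-30T17:45:30Z","text":"@u5968 w118 w118 w118 w270 w260 w403 w121 w162 w043 w079 w402 w334 w270 w043 w270 w118 https://t.co/oemckmemvp"}
{"tweet_id":"t00000022","user_id":"u000005","created_at":"2022-02-02T06:20:51Z","text":"w419 w108 w419 w419 w322 w452 w395 w358 w420 w043 w135 w420 w419 w121 w027 w419"}
{"tweet_id":"t00000023","user_id":"u000014","created_at":"2021-11-11T09:24:43Z","text":"w118 w419 w257 w403 w420 w402 w419 w420 w162 w419 w362 w009 w420 w419 w419 w027 https://t.co/gz5h8b0jv4"}
{"tweet_id":"t00000024","user_id":"u000015","created_at":"2020-11-10T10:55:48Z","text":"w301 w118 w260 w118 w473 w473 w118 w420 w420 w118 w324 w473 w473 w402 azithromycin superb"}
{"tweet_id":"t00000025","user_id":"u000012","created_at":"2021-12-06T13:51:59Z","text":"@u9383 w118 w118 w473 w118 w118 w419 w118 w473 w118 w118 w118 w402 w270 w118 w402 w118"}
{"tweet_id":"t00000026","user_id":"u000011","created_at":"2021-07-14T17:47:29Z","text":"w375 w375 w375 w043 w011 w124 w382 w043 w375 w124 w497 w270 w118 w162 w480 w043 https://t.co/hlgtlvsehm"}
{"tweet_id":"t00000027","user_id":"u000011","created_at":"2020-09-28T18:36:32Z","text":"@u0842 w473 w079 w270 w241 w324 w491 w270 w098 w270 w270 w270 w270 w118 w121 w408 w118"}
{"tweet_id":"t00000028","user_id":"u000001","created_at":"2021-02-20T17:11:41Z","text":"@u6882 w375 w002 w118 w162 w402 w402 w279 w118 w375 w118 w402 w473 w402 w118 w043 w188"}
{"tweet_id":"t00000029","user_id":"u000008","created_at":"2020-12-27T14:28:53Z","text":"w257 w108 w266 w112 nausea superb w295 w358 w419 w373 w108 w121 w359 w295 remdesivir superb https://t.co/q76fb31quj"}
{"tweet_id":"t00000030","user_id":"u000014","created_at":"2020-04-29T04:16:42Z","text":"w359 w121 w266 w121 w180 w266 w121 w358 cough superb w266 w266 w414 w359 w118 w373 https://t.co/b8joisixcl"}
{"tweet_id":"t00000031","user_id":"u000003","created_at":"2021-11-06T17:26:52Z","text":"@u7752 w079 w473 w473 w043 w491 w324 w382 w118 w098 w279 w291 w382 w420 w043 w375 w279"}
{"tweet_id":"t00000032","user_id":"u000009","created_at":"2020-07-09T10:35:01Z","text":"w121 w474 w176 w118 w403 w021 w118 w162 w162 w089 w375 w139 w162 w118 ivm w118"}
{"tweet_id":"t00000033","user_id":"u000018","created_at":"2021-10-18T05:50:25Z","text":"w295 w474 w375 w452 w375 w362 w188 w452 w108 w043 w089 w403 w497 w324 w375 w480"}
{"tweet_id":"t00000034","user_id":"u000001","created_at":"2020-12-20T13:11:43Z","text":"@u1028 w419 w270 w420 w322 w362 w362 w419 w420 w079 w079 w155 w419 w420 w452 w419 w362"}
{"tweet_id":"t00000035","user_id":"u000012","created_at":"2020-03-13T12:08:49Z","text":"w373 w121 w118 w197 w382 w118 w358 w266 w124 w079 zinc w121 w491 w358 w473 w375 https://t.co/cyad9ezi04"}
{"tweet_id":"t00000036","user_id":"u000006","created_at":"2021-06-22T08:45:08Z","text":"@u8017 w043 w375 w375 w043 w162 w188 w027 w121 w270 w043 w291 w497 w162 w375 w043 w043"}
{"tweet_id":"t00000037","user_id":"u000017","created_at":"2021-05-14T00:27:19Z","text":"@u7039 w473 w121 w118 w118 w474 w118 w009 w043 w270 w260 w118 w118 w419 w473 w118 w162"}
{"tweet_id":"t00000038","user_id":"u000007","created_at":"2022-02-08T12:10:53Z","text":"w108 w121 w027 w295 w266 w456 w373 w414 w373 w266 w121 w121 w452 w108 w266 w257"}
{"tweet_id":"t00000039","user_id":"u000012","created_at":"2020-03-30T09:15:41Z","text":"w021 w043 w043 w375 w375 w079 w079 w162 w162 w324 w121 w375 w089 w295 w375 w375 https://t.co/klgla07bu9"}
{"tweet_id":"t00000040","user_id":"u000019","created_at":"2021-11-24T13:00:07Z","text":"@u6437 w359 w266 w065 w324 w266 w118 w324 w420 w121 w420 w359 w118 w266 w266 w419 w452"}
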